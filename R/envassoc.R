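# Per-epilocus logistic environmental association with Wald and G
# (likelihood-ratio) model selection, in the style of landscape-genomics
# association scans: marker ~ constant + one standardized environmental
# variable, candidate when BOTH tests pass the corrected threshold.

#' Null (intercept-only) logistic fit
#'
#' Closed form: `beta0 = logit(mean(y))`,
#' `loglik = n * (p log p + (1-p) log(1-p))`.
#'
#' @param y Binary response vector.
#' @return List with `beta0`, `loglik`, `monomorphic` flag (TRUE when `y`
#'   is constant; such loci are skipped upstream).
#' @export
fit_null <- function(y) {
  stopifnot(all(y %in% c(0, 1)))
  p <- mean(y)
  if (p %in% c(0, 1))
    return(list(beta0 = NA_real_, loglik = 0, monomorphic = TRUE))
  n <- length(y)
  list(beta0 = stats::qlogis(p),
       loglik = n * (p * log(p) + (1 - p) * log(1 - p)),
       monomorphic = FALSE)
}

#' Univariate logistic association fit
#'
#' Maximum-likelihood logistic regression of a binary marker on one
#' (standardized) environmental variable by iteratively reweighted least
#' squares, with Wald and G statistics against the intercept-only null.
#' Complete or quasi-complete separation (diverging slope) is flagged and
#' such fits are excluded from candidate screens.
#'
#' @param y Binary response.
#' @param x Numeric covariate (standardize beforehand so slopes are
#'   scale-free).
#' @param max_iter IRLS iteration cap.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return List of class `logistic_association`: `beta0`, `beta1`, `se1`,
#'   `loglik_full`, `loglik_null`, `wald` (`(beta1/se1)^2`), `g`
#'   (`2 * (llf - ll0)`), `p_wald`, `p_g`, `pseudo_r2` (Nagelkerke),
#'   `converged`, `separated`, `monomorphic`.
#' @export
fit_logistic <- function(y, x, max_iter = 50, tol = 1e-10) {
  stopifnot(all(y %in% c(0, 1)), length(y) == length(x))
  if (length(y) < 10) stop("need n >= 10 observations")
  null <- fit_null(y)
  if (null$monomorphic)
    return(structure(list(monomorphic = TRUE, separated = FALSE,
                          converged = FALSE), class = "logistic_association"))
  X <- cbind(1, x)
  beta <- c(null$beta0, 0)
  ll <- null$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- mu * (1 - mu)
    info <- crossprod(X, wt * X)
    if (rcond(info) < 1e-12) break
    beta_new <- beta + solve(info, crossprod(X, y - mu))
    eta_new <- drop(X %*% beta_new)
    ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
    if (!is.finite(ll_new)) break
    # step-halve if the likelihood decreases
    half <- 0
    while (ll_new < ll && half < 10) {
      beta_new <- (beta + beta_new) / 2
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
      half <- half + 1
    }
    done <- abs(ll_new - ll) < tol
    beta <- drop(beta_new); ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, (mu * (1 - mu)) * X)
  se1 <- if (rcond(info) > 1e-12) sqrt(solve(info)[2, 2]) else Inf
  separated <- !converged && abs(beta[2]) > 10 ||
    abs(beta[2]) > 15 || !is.finite(se1)
  g <- max(0, 2 * (ll - null$loglik))
  wald <- (beta[2] / se1)^2
  n <- length(y)
  r2 <- (1 - exp(2 * (null$loglik - ll) / n)) /
    (1 - exp(2 * null$loglik / n))
  beta <- unname(beta)
  structure(list(beta0 = beta[1], beta1 = beta[2], se1 = se1,
                 loglik_full = ll, loglik_null = null$loglik,
                 wald = wald, g = g,
                 p_wald = stats::pchisq(wald, 1, lower.tail = FALSE),
                 p_g = stats::pchisq(g, 1, lower.tail = FALSE),
                 pseudo_r2 = r2, n = n,
                 converged = converged, separated = separated,
                 monomorphic = FALSE),
            class = "logistic_association")
}

#' @export
print.logistic_association <- function(x, ...) {
  if (isTRUE(x$monomorphic)) {
    cat("logistic_association: monomorphic marker (skipped)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "logit(p) = %.3f + %.3f x | Wald = %.2f (p = %.3g), G = %.2f (p = %.3g), R2 = %.3f%s\n",
    x$beta0, x$beta1, x$wald, x$p_wald, x$g, x$p_g, x$pseudo_r2,
    if (x$separated) " [separated]" else ""))
  invisible(x)
}

#' Pseudo-R-squared of a fitted association
#'
#' Nagelkerke (default): `[1 - exp(2 (ll0 - ll1)/n)] / [1 - exp(2 ll0/n)]`;
#' McFadden: `1 - ll1/ll0`.
#'
#' @param assoc A fitted `logistic_association`.
#' @param method `"nagelkerke"` or `"mcfadden"`.
#' @return Numeric in `[0, 1]`.
#' @export
pseudo_r2 <- function(assoc, method = c("nagelkerke", "mcfadden")) {
  method <- match.arg(method)
  if (isTRUE(assoc$monomorphic)) return(NA_real_)
  if (method == "nagelkerke") {
    (1 - exp(2 * (assoc$loglik_null - assoc$loglik_full) / assoc$n)) /
      (1 - exp(2 * assoc$loglik_null / assoc$n))
  } else {
    1 - assoc$loglik_full / assoc$loglik_null
  }
}

#' Candidate selection for one fitted association
#'
#' A locus x variable pair is a candidate iff BOTH the Wald and the G test
#' pass the multiplicity-corrected threshold (the strict conjunction
#' convention) and the fit is neither separated nor monomorphic.
#'
#' @param assoc A fitted `logistic_association`.
#' @param alpha Family-wise (or FDR) level.
#' @param n_tests Number of tests in the family.
#' @param correction `"bonferroni"` (default) or `"none"`. (BH operates on
#'   whole p-value vectors; see [screen_all()].)
#' @return Logical.
#' @export
model_selection <- function(assoc, alpha = 0.05, n_tests = 1,
                            correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (isTRUE(assoc$monomorphic) || isTRUE(assoc$separated)) return(FALSE)
  thr <- if (correction == "bonferroni") alpha / n_tests else alpha
  assoc$p_wald < thr && assoc$p_g < thr
}

#' Environmental association screen over all epiloci
#'
#' Fits every polymorphic epilocus against every (standardized)
#' environmental variable, applies the conjunction Wald+G selection under
#' the chosen multiplicity correction, and tabulates candidate counts per
#' panel x variable.
#'
#' @param em An `epilocus_matrix` or [analysis_view()] list.
#' @param metadata Data frame containing the variables.
#' @param variables Column names of the environmental variables (default
#'   `c("elevation", "amt", "ap")`).
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return List of class `candidate_screen` with `tests` (per locus x
#'   variable table), `counts` (panel x variable candidate counts),
#'   `n_tests`, `alpha`, `correction`.
#' @export
screen_all <- function(em, metadata,
                       variables = c("elevation", "amt", "ap"),
                       alpha = 0.05,
                       correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  v <- if (inherits(em, "epilocus_matrix")) analysis_view(em) else em
  x <- v$x
  stopifnot(nrow(metadata) == nrow(x))
  missing_vars <- setdiff(variables, names(metadata))
  if (length(missing_vars))
    stop("metadata lacks variable(s): ", paste(missing_vars, collapse = ", "))
  const <- vapply(variables, function(vn) stats::sd(metadata[[vn]]) == 0,
                  logical(1))
  if (any(const)) {
    warning("constant variable(s) skipped: ",
            paste(variables[const], collapse = ", "))
    variables <- variables[!const]
  }
  z <- lapply(variables, function(vn) standardize(metadata[[vn]], vn))
  names(z) <- variables
  poly <- which(colMeans(x) > 0 & colMeans(x) < 1)
  rows <- vector("list", length(poly) * length(variables))
  k <- 0
  for (j in poly) {
    yj <- x[, j]
    for (vn in variables) {
      fit <- fit_logistic(yj, z[[vn]])
      k <- k + 1
      rows[[k]] <- data.frame(
        locus = colnames(x)[j], panel = v$panel[j], variable = vn,
        beta0 = fit$beta0, beta1 = fit$beta1,
        wald = fit$wald, g = fit$g, p_wald = fit$p_wald, p_g = fit$p_g,
        pseudo_r2 = fit$pseudo_r2, separated = fit$separated,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, c(rows[seq_len(k)], make.row.names = FALSE))
  n_tests <- nrow(tests)
  usable <- !tests$separated
  if (correction == "bonferroni") {
    sig <- usable & tests$p_wald < alpha / n_tests &
      tests$p_g < alpha / n_tests
  } else {
    adj_w <- stats::p.adjust(tests$p_wald, "BH")
    adj_g <- stats::p.adjust(tests$p_g, "BH")
    sig <- usable & adj_w < alpha & adj_g < alpha
  }
  tests$significant <- sig
  counts <- as.data.frame(table(panel = tests$panel[sig],
                                variable = tests$variable[sig]))
  structure(list(tests = tests, counts = counts, n_tests = n_tests,
                 alpha = alpha, correction = correction),
            class = "candidate_screen")
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf("candidate screen: %d tests, %d candidates (%s, alpha %.3g)\n",
              x$n_tests, sum(x$tests$significant), x$correction, x$alpha))
  if (sum(x$tests$significant))
    print(x$counts[x$counts$Freq > 0, ], row.names = FALSE)
  invisible(x)
}
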