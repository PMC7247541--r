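# Published group x panel diversity summary of the emulated MSAP study
# (study-level summary statistics used as inputs for arithmetic checks).
# Columns: combined group, epilocus panel, marker total, polymorphic count,
# private polymorphic count, panel-mean Shannon index.
group	panel	n_total	n_polymorphic	n_private	shannon_mean
2xS	nonmethylated	268	162	40	0.285
2xM	nonmethylated	268	85	6	0.248
4xM	nonmethylated	268	190	64	0.326
4xA	nonmethylated	268	48	2	0.109
2xS	external	378	260	53	0.323
2xM	external	378	180	14	0.358
4xM	external	378	242	56	0.311
4xA	external	378	62	6	0.088
2xS	internal	442	260	46	0.235
2xM	internal	442	139	4	0.228
4xM	internal	442	197	20	0.173
4xA	internal	442	309	69	0.325
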