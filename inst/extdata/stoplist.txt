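# Frequent non-entity words stripped from multi-word entity phrases before
# word-level entity lookup. Replaceable via refinement_config().
protein
proteins
gene
genes
factor
factors
suppressor
activator
repressor
regulator
operon
promoter
product
enzyme
region
site
complex
subunit
domain
family
element
sequence
transcript
receptor
kinase
pathway
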