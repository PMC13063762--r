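# Synthetic example of a curated stress-responsive gene list, matching the
# gene ids produced by sim_config()/generate_truth(). Real analyses supply
# their own list of hypoxia-/salt-responsive genes, one id per line;
# '#' starts a comment.
gene_00001
gene_00002
gene_00010  # e.g. an alcohol-dehydrogenase-like hypoxia marker
gene_00025
gene_00100
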