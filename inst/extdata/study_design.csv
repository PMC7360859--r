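receptor,start_structure,n_seed_clusters,clone_length_ns,printed_aggregate_us
B4.2.3,5IVX,218,100,21.8
MAIT,5U2V,287,100,28.7
003,6FR4,182,100,NA
E8,2IAM,93,100,9.3
42F3,3TJH,230,100,23.0
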