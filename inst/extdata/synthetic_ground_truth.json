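{"hub":null,"enriched_disease":"Disease 0001","query_set":["hsa-miR-0040-3p","hsa-miR-0023-5p","hsa-miR-0035-5p","hsa-miR-0025-5p","hsa-miR-0028-3p"],"cliques":null}
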