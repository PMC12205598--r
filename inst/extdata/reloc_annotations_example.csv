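protein,pair_id,relocalized,destination,own_wt_compartment,paralog_wt_compartment,abundance_class
CUE4,CUE1-CUE4,TRUE,cytoplasm,ER,cytoplasm,increase
GGA1,GGA1-GGA2,TRUE,Golgi,cytoplasm,Golgi,ns
HMS2,HMS2-SKN7,TRUE,cytoplasm,nucleus,nucleus,ns
POR2,POR1-POR2,TRUE,cytoplasm,mitochondrion,mitochondrion,increase
RPL40B,RPL40A-RPL40B,TRUE,cytoplasm,nucleus,cytoplasm,increase
RPS22A,RPS22A-RPS22B,TRUE,vacuole,cytoplasm,cytoplasm,decrease
RPS22B,RPS22A-RPS22B,TRUE,vacuole,cytoplasm,cytoplasm,decrease
UPA1,UPA1-UPA2,TRUE,nucleus,cytoplasm,cytoplasm,ns
UPA2,UPA1-UPA2,TRUE,nucleus,cytoplasm,cytoplasm,ns
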