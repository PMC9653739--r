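((Campanulaceae_sp:1,Cyphiaceae_sp:1)outgroup:1,((Lobelia_baumannii:1,Colensoa_physaloides:1)baumannii_clade:1,(Monopsis_lutea:1,(Grammatotheca_bergiana:1,(Lobelia_thermalis:1,(Lobelia_galpinii:1,(Lobelia_jasionoides:1,(Lobelia_laxa:1,(Lobelia_fervens:1,Lobelia_erinus:1)inv5_interval:1)inv34_interval:1)post_inv2_crown:1)inv2_interval:1)inv1_crown:1)grammatotheca_stem:1)inv1_interval:1)lobeliaceae:1)root;
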