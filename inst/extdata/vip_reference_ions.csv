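vip_id,source_species,litter_type,rt_min,observed_mz,adduct,reported_ion_formula,neutral_formula,reported_ppm,isotope_peak,consistent,putative_id
M615T468,Qilex,AD,7.80,615.0987,[M-H]-,C28H23O16,C28H24O16,0.9,0,TRUE,Quercetin-3-O-(6''-O-galloyl)-b-D-glucopyranoside
M629T496,Qilex,AD,8.26,629.1144,[M-H]-,C29H25O16,C29H26O16,1.1,0,TRUE,Isorhamnetin 3-(6''-galloylglucoside)
M340T388,Qilex,AD,6.47,339.0717,[M-H]-,C15H15O9,C15H16O9,1.5,0,TRUE,Aesculin
M387T49,Qilex,ND,0.81,387.1143,[M+HCOO]-,C13H23O13,C12H22O11,0.5,0,TRUE,Disaccharide
M387T49,Qilex,ND,0.81,341.1086,[M-H]-,C12H21O11,C12H22O11,0.9,0,TRUE,Disaccharide
M330T66,Qilex,AD,1.09,331.0671,[M-H]-,C13H15O10,C13H16O10,-0.5,0,TRUE,Galloyl-b-D-glucose
M399T407,Qilex,AD,6.78,399.0934,[M+HCOO]-,C16H17O9,C16H18O9,-3.9,0,TRUE,Chlorogenic acid
M399T407,Qilex,AD,6.78,353.0875,[M-H]-,C17H19O1,C16H18O9,-3.3,0,TRUE,Chlorogenic acid
M711T533,Qpubescens,AD,8.88,711.3964,[M+HCOO]-,C37H59O13,C36H58O11,-0.5,0,TRUE,Arjungenin glycoside isomer 1
M711T533,Qpubescens,AD,8.88,665.3906,[M-H]-,C36H57O11,C36H58O11,4.6,0,TRUE,Arjungenin glycoside isomer 1
M711T496,Qpubescens,AD,8.26,711.3965,[M+HCOO]-,C37H59O13,C36H58O11,-0.9,0,TRUE,Arjungenin glycoside isomer 2
M711T496,Qpubescens,AD,8.26,665.3906,[M-H]-,C36H57O11,C36H58O11,-5.5,0,TRUE,Arjungenin glycoside isomer 2
M503T633,Qpubescens,AD,10.55,503.3382,[M-H]-,C30H47O6,C30H48O6,-0.5,0,TRUE,Oleanane triterpene
M695T600,Qpubescens,AD,10.00,695.4018,[M+HCOO]-,C37H59O12,C36H58O10,-1.4,0,TRUE,Arjunglucoside II or arjunetin
M695T600,Qpubescens,AD,10.00,649.3957,[M-H]-,C36H57O10,C36H58O10,-2.7,0,TRUE,Arjunglucoside II or arjunetin
M387T49,Qpubescens,ND,0.81,387.1144,[M+HCOO]-,C13H23O13,C12H22O11,0.5,0,TRUE,Disaccharide
M702T383,Qpubescens,ND,6.38,701.5749,[M-2H]2-,C57H46O42,C57H48O42,0.9,1,TRUE,Ellagitannin
M593T520,Qpubescens,AD,8.66,593.1591,[M-2H]2-,C60H50O26,C60H52O26,-1.6,0,FALSE,Proanthocyanidin
M343T637,Qpubescens,AD,10.61,343.0460,[M-H]-,C17H11O8,C17H12O8,0.3,0,TRUE,Galloylquinic acid isomer
M289T405,Qpubescens,AD,6.74,289.0716,[M-H]-,C15H14O6,C15H14O6,1.6,0,TRUE,(epi)catechin
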