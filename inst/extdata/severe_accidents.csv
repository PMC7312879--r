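date,company,accident_type,deaths,serious_injuries,direct_loss_yuan
2004-04-08,Zhongrun Iron and Steel Co. Ltd.,Electric shock,12,3,
2006-11-08,Yongqiang Roller Co. Ltd.,Thermal injury,12,15,
2007-04-18,Qinghe Special Steel Co. Ltd.,Thermal injury,32,6,
2007-08-19,Weiqiao Pioneering Groups Co. Ltd.,Other explosion,20,55,
2008-12-24,Tangshan Ganglu Iron and Steel Co. Ltd.,Poisoning and asphyxiation,17,27,
2010-01-04,Puyang Iron and Steel Co. Ltd.,Poisoning and asphyxiation,21,9,
2011-10-05,Nanjing Iron and Steel Union Co. Ltd.,Thermal injury,12,1,
2012-02-20,Anshan Iron and Steel Group,Other explosion,13,17,
2012-08-05,Aluminum lock processing plant,Other explosion,13,14,
2015-11-29,Shandong Fulai Stainless Steel Co. Ltd.,Poisoning and asphyxiation,10,7,
2016-01-22,Henan branch of China aluminum corporation,Fall from a high place,13,6,
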