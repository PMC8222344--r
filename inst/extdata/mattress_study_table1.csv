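mattress,centering,table_height_mm,offcentre_mean_mm,offcentre_sd_mm,back_to_pad_mean_mm,back_to_pad_sd_mm,width_mm
none,automatic,120,11,7,NA,NA,309
grey,automatic,136,39,11,33,5,327
grey,manual,183.5,12,8,NA,NA,299
orange,automatic,164,50,13,103,14,332
orange,manual,220,13,8,NA,NA,299
double,automatic,204.5,71,12,163,20,344
double,manual,268,15,8,NA,NA,307
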