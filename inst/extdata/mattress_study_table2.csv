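mattress,centering,ctdi_vol_mgy,mas_mean,mas_sd
none,automatic,8.68,150,41
grey,automatic,10.66,186,56
grey,manual,8.71,153,42
orange,automatic,11.33,197,61
orange,manual,9.04,157,46
double,automatic,12.28,214,66
double,manual,9.71,168,50
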