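city_id,a_d,b_d,a_s,b_s,withdraw_reach,return_reach
zaragoza,9.63880597014925,0.0323358208955224,0.4,0.0138582089552239,421,426
logrono,9.63880597014925,0.0482624192470483,0.4,0.0206838939630207,274,406
tortosa_urban,9.63880597014925,0.0951053555750658,0.4,0.0407594381035997,426,428
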