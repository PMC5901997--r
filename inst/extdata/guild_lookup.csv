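genus,max_size_um,guild
Achnanthes,,low_profile
Amphora,,low_profile
Cocconeis,,low_profile
Entomoneis,,motile
Halamphora,,low_profile
Labellicula,,motile
Licmophora,,high_profile
Mastogloia,,motile
Navicula,,motile
Nitzschia,,motile
Olifantiella,,motile
Pseudo-nitzschia,,planktonic
Thalassiosira,,planktonic
Tursicola,,high_profile
Gomphonema,,high_profile
Fragilaria,25,low_profile
Fragilaria,,high_profile
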