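species	anchor
Olea_europaea	V29
Olea_europaea	F45
Olea_europaea	I53
Olea_europaea	L68
Olea_europaea	L70
Olea_europaea	M76
Olea_europaea	I86
Olea_europaea	I95
Betula_pendula	V28
Betula_pendula	W35
Betula_pendula	F41
Betula_pendula	F44
Betula_pendula	L69
Betula_pendula	M75
Betula_pendula	I94
Corylus_avellana	V28
Corylus_avellana	W35
Corylus_avellana	L69
Corylus_avellana	M75
Corylus_avellana	I94
Phleum_pratense	F42
Phleum_pratense	M65
Phleum_pratense	F66
Phleum_pratense	V67
Phleum_pratense	M73
Phleum_pratense	I92
Zea_mays	V26
Zea_mays	F39
Zea_mays	F59
Zea_mays	L65
Zea_mays	L67
Zea_mays	M73
Zea_mays	I83
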