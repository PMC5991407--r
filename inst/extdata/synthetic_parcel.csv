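"parcel_id","year","composite","ndvi","reliability"
"synthetic_parcel",2001,1,0.1802,1
"synthetic_parcel",2001,2,0.1806,0
"synthetic_parcel",2001,3,0.182,0
"synthetic_parcel",2001,4,0.1858,0
"synthetic_parcel",2001,5,0.1949,1
"synthetic_parcel",2001,6,0.2142,0
"synthetic_parcel",2001,7,0.2504,0
"synthetic_parcel",2001,8,0.3097,0
"synthetic_parcel",2001,9,0.3938,1
"synthetic_parcel",2001,10,0.4954,0
"synthetic_parcel",2001,11,0.5964,0
"synthetic_parcel",2001,12,0.6719,0
"synthetic_parcel",2001,13,0.7,0
"synthetic_parcel",2001,14,0.6719,0
"synthetic_parcel",2001,15,0.5964,0
"synthetic_parcel",2001,16,0.4954,0
"synthetic_parcel",2001,17,0.3938,0
"synthetic_parcel",2001,18,0.3097,0
"synthetic_parcel",2001,19,0.2504,0
"synthetic_parcel",2001,20,0.2142,1
"synthetic_parcel",2001,21,0.1949,0
"synthetic_parcel",2001,22,0.1858,0
"synthetic_parcel",2001,23,0.182,0
"synthetic_parcel",2002,1,0.1802,0
"synthetic_parcel",2002,2,NA,NA
"synthetic_parcel",2002,3,0.182,0
"synthetic_parcel",2002,4,0.1858,0
"synthetic_parcel",2002,5,0.1949,0
"synthetic_parcel",2002,6,0.2142,1
"synthetic_parcel",2002,7,0.2504,0
"synthetic_parcel",2002,8,0.3097,0
"synthetic_parcel",2002,9,0.3938,0
"synthetic_parcel",2002,10,0.4954,0
"synthetic_parcel",2002,11,0.5964,0
"synthetic_parcel",2002,12,0.6719,0
"synthetic_parcel",2002,13,0.7,0
"synthetic_parcel",2002,14,0.6719,0
"synthetic_parcel",2002,15,0.5964,0
"synthetic_parcel",2002,16,0.4954,1
"synthetic_parcel",2002,17,0.3938,0
"synthetic_parcel",2002,18,0.3097,1
"synthetic_parcel",2002,19,0.2504,0
"synthetic_parcel",2002,20,0.2142,1
"synthetic_parcel",2002,21,0.1949,0
"synthetic_parcel",2002,22,0.1858,0
"synthetic_parcel",2002,23,0.182,0
"synthetic_parcel",2003,1,0.1802,0
"synthetic_parcel",2003,2,NA,NA
"synthetic_parcel",2003,3,0.182,0
"synthetic_parcel",2003,4,0.1858,0
"synthetic_parcel",2003,5,0.1949,0
"synthetic_parcel",2003,6,0.2142,1
"synthetic_parcel",2003,7,0.2504,0
"synthetic_parcel",2003,8,0.3097,0
"synthetic_parcel",2003,9,0.3938,0
"synthetic_parcel",2003,10,0.4954,0
"synthetic_parcel",2003,11,0.5964,1
"synthetic_parcel",2003,12,0.6719,1
"synthetic_parcel",2003,13,0.7,0
"synthetic_parcel",2003,14,0.6719,0
"synthetic_parcel",2003,15,0.5964,1
"synthetic_parcel",2003,16,0.4954,0
"synthetic_parcel",2003,17,0.3938,0
"synthetic_parcel",2003,18,0.3097,0
"synthetic_parcel",2003,19,0.2504,0
"synthetic_parcel",2003,20,0.2142,0
"synthetic_parcel",2003,21,0.1949,0
"synthetic_parcel",2003,22,0.1858,0
"synthetic_parcel",2003,23,0.182,1
"synthetic_parcel",2004,1,0.1802,0
"synthetic_parcel",2004,2,0.1806,0
"synthetic_parcel",2004,3,0.182,0
"synthetic_parcel",2004,4,0.1858,0
"synthetic_parcel",2004,5,0.1949,0
"synthetic_parcel",2004,6,0.2142,1
"synthetic_parcel",2004,7,0.2504,0
"synthetic_parcel",2004,8,0.3097,0
"synthetic_parcel",2004,9,0.3938,0
"synthetic_parcel",2004,10,0.4954,0
"synthetic_parcel",2004,11,0.5964,0
"synthetic_parcel",2004,12,0.6719,1
"synthetic_parcel",2004,13,0.7,0
"synthetic_parcel",2004,14,0.6719,0
"synthetic_parcel",2004,15,0.5964,0
"synthetic_parcel",2004,16,0.4954,1
"synthetic_parcel",2004,17,0.3938,0
"synthetic_parcel",2004,18,0.3097,0
"synthetic_parcel",2004,19,0.2504,0
"synthetic_parcel",2004,20,0.2142,0
"synthetic_parcel",2004,21,0.1949,1
"synthetic_parcel",2004,22,0.1858,0
"synthetic_parcel",2004,23,0.182,0
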