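"parcel_id","area_ha"
"synthetic_parcel",320
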