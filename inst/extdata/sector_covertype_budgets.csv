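# Published growing-season (113-day) budget summary for a rewetted extracted
# fen in southeastern Manitoba: per-sector, per-cover-type means (SD) of NEE
# (g CO2 m-2), CH4 (g CH4 m-2), total C (g C m-2) and GWP (g CO2-e m-2), with
# the cover weights from the site-level vegetation survey, plus the printed
# cover-weighted ALL rows. Sectors: UNR unrestored; RP1 one season after
# rewetting and profiling; R1 one season after rewetting; R10 ten seasons
# after rewetting; REF reference fen.
sector,cover_type,n_chambers,weight,nee,nee_sd,ch4,ch4_sd,c,c_sd,gwp,gwp_sd
UNR,bare,3,0.82,170,69,0.3,0.2,47,19,177,73
UNR,herbaceous,3,0.18,-181,66,1.9,1.6,-48,18,-130,77
UNR,ALL,6,1.00,107,68,0.5,0.5,30,19,122,73
RP1,open_water,6,1.00,138,108,8.7,8.7,44,30,373,258
R1,bare,3,0.15,-102,231,9.4,8.6,-21,62,152,292
R1,herbaceous,3,0.66,-1175,255,11.0,6.9,-312,71,-879,354
R1,shrubs,3,0.19,-1061,235,7.3,8.1,-284,64,-864,305
R1,ALL,9,1.00,-992,248,10.0,7.4,-263,68,-722,335
R10,herbaceous,3,0.98,-1053,323,26.8,10.2,-267,80,-329,53
R10,shrubs,3,0.02,-1437,318,33.3,6.4,-367,87,-539,358
R10,ALL,6,1.00,-1060,322,26.9,10.1,-269,81,-333,59
REF,shrubs,5,0.47,-493,371,6.6,4.2,-130,100,-315,319
REF,herbaceous,4,0.53,-683,483,8.6,5.6,-180,130,-452,425
REF,ALL,9,1.00,-594,430,7.6,4.9,-156,116,-388,376
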