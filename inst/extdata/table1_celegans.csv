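strain,method,input_ng,replicate,value,note
MY16,wgs_published,NA,1,68,
MY16,chef,NA,1,56,
MY16,chef,NA,2,76,avg_two_bands
MY16,chef,NA,3,71,avg_two_bands
MY16,rr,10,1,65,
MY16,gcc,10,1,64,
MY16,rr,10,2,60,
MY16,gcc,10,2,64,
MY16,rr,10,3,78,
MY16,gcc,10,3,79,
MY16,rr,50,1,110,
MY16,gcc,50,1,87,
MY16,rr,50,2,110,
MY16,gcc,50,2,89,
MY16,rr,50,3,91,
MY16,gcc,50,3,81,
JU775,wgs_published,NA,1,70,
JU775,chef,NA,1,63,
JU775,chef,NA,2,81,
JU775,chef,NA,3,66,
JU775,rr,10,1,100,
JU775,gcc,10,1,93,
JU775,rr,10,2,78,
JU775,gcc,10,2,79,
JU775,rr,10,3,93,
JU775,gcc,10,3,96,
JU775,rr,50,1,139,
JU775,gcc,50,1,112,
JU775,rr,50,2,138,
JU775,gcc,50,2,110,
JU775,rr,50,3,110,
JU775,gcc,50,3,102,
ED3042,wgs_published,NA,1,105,
ED3042,chef,NA,1,104,
ED3042,chef,NA,2,111,
ED3042,chef,NA,3,106,
ED3042,rr,10,1,88,
ED3042,gcc,10,1,106,
ED3042,rr,10,2,76,
ED3042,gcc,10,2,90,
ED3042,rr,10,3,119,
ED3042,gcc,10,3,129,
ED3042,rr,50,1,206,
ED3042,gcc,50,1,155,
ED3042,rr,50,2,202,
ED3042,gcc,50,2,151,
ED3042,rr,50,3,167,
ED3042,gcc,50,3,141,
ED3040,wgs_published,NA,1,149,
ED3040,chef,NA,1,146,
ED3040,chef,NA,2,156,
ED3040,chef,NA,3,160,
ED3040,rr,10,1,121,
ED3040,gcc,10,1,154,
ED3040,rr,10,2,127,
ED3040,gcc,10,2,138,
ED3040,rr,10,3,182,
ED3040,gcc,10,3,187,
ED3040,rr,50,1,281,
ED3040,gcc,50,1,224,
ED3040,rr,50,2,279,
ED3040,gcc,50,2,216,
ED3040,rr,50,3,234,
ED3040,gcc,50,3,204,
MY6,wgs_published,NA,1,193,
MY6,chef,NA,1,201,
MY6,chef,NA,2,217,
MY6,chef,NA,3,229,
MY6,rr,10,1,191,
MY6,gcc,10,1,194,
MY6,rr,10,2,161,
MY6,gcc,10,2,173,
MY6,rr,10,3,243,
MY6,gcc,10,3,248,
MY6,rr,50,1,356,
MY6,gcc,50,1,285,
MY6,rr,50,2,351,
MY6,gcc,50,2,283,
MY6,rr,50,3,302,
MY6,gcc,50,3,265,
MY14,wgs_published,NA,1,237,
MY14,chef,NA,1,236,
MY14,chef,NA,2,253,
MY14,chef,NA,3,267,
MY14,rr,10,1,266,
MY14,gcc,10,1,259,
MY14,rr,10,2,202,
MY14,gcc,10,2,202,
MY14,rr,10,3,263,
MY14,gcc,10,3,273,
MY14,rr,50,1,419,
MY14,gcc,50,1,319,
MY14,rr,50,2,415,
MY14,gcc,50,2,319,
MY14,rr,50,3,341,
MY14,gcc,50,3,291,
PX174,wgs_published,NA,1,298,
PX174,chef,NA,1,NA,
PX174,chef,NA,2,306,
PX174,chef,NA,3,340,
PX174,rr,10,1,260,
PX174,gcc,10,1,252,
PX174,rr,10,2,154,
PX174,gcc,10,2,186,
PX174,rr,10,3,309,
PX174,gcc,10,3,304,
PX174,rr,50,1,429,
PX174,gcc,50,1,343,
PX174,rr,50,2,425,
PX174,gcc,50,2,335,
PX174,rr,50,3,355,
PX174,gcc,50,3,316,
MY1,wgs_published,NA,1,418,
MY1,chef,NA,1,410,
MY1,chef,NA,2,396,
MY1,chef,NA,3,431,
MY1,rr,10,1,370,
MY1,gcc,10,1,359,
MY1,rr,10,2,303,
MY1,gcc,10,2,323,
MY1,rr,10,3,414,
MY1,gcc,10,3,427,
MY1,rr,50,1,603,
MY1,gcc,50,1,489,
MY1,rr,50,2,585,
MY1,gcc,50,2,475,
MY1,rr,50,3,493,
MY1,gcc,50,3,449,
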