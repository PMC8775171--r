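label,starch,protein,lipid,ash,moisture,basis
CP raw,39.73,19.39,7.29,2.17,3.89,as-is
PE raw,40.90,19.73,2.79,1.87,7.43,as-is
BB raw,33.34,20.64,2.45,3.70,7.23,as-is
CP WSM 30,41.24,19.65,NA,NA,NA,dry-matter
PE WSM 30,45.48,17.60,NA,NA,NA,dry-matter
BB WSM 60,38.61,18.67,NA,NA,NA,dry-matter
PE ICC 30,61.21,17.74,NA,NA,NA,dry-matter
CP ICC 30,54.96,16.94,NA,NA,NA,dry-matter
CP ICC 60,55.33,16.57,NA,NA,NA,dry-matter
CP ICC 90,54.56,17.33,NA,NA,NA,dry-matter
BB ICC 60,47.64,19.98,NA,NA,NA,dry-matter
BB ICC 90,51.31,21.06,NA,NA,NA,dry-matter
BB ICC 120,50.44,22.10,NA,NA,NA,dry-matter
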