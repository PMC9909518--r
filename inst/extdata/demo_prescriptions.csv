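MEDICATION,YEAR,STRUCTURE,ATC_L5
PARACETAMOL HEXAL 500 mg Tabletten | (Paracetamol),2018,TRUE,N02BE01
IBUPROFEN STADA 600 mg Zäpfchen | (Ibuprofen),2019,TRUE,M01AE01
METAMIZOL HEXAL 500 mg Tropfen | (Metamizol),2019,TRUE,N02BB02
PANTOPRAZOL AL 40 mg Tabletten | (Pantoprazol),2020,TRUE,A02BC02
Ibuprofen 600,2018,FALSE,
Ibuprofen 600,2019,FALSE,
Ibuprofen,2019,FALSE,
Paracetamol 500,2017,FALSE,
Stada paracetamol,2020,FALSE,
ARILIN 500 Filmtabletten | (Metronidazol),2016,FALSE,
NaCl 0.9%,2018,FALSE,
NaCL 0.9%,2019,FALSE,
Telmisartan 80,2020,FALSE,
Pantoprazol,2016,FALSE,
BGA,2019,FALSE,
BGA arteriell,2020,FALSE,
BE abnehmen,2018,FALSE,
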