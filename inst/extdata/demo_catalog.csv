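Product_name,Ingredient_name,Atc_code
IBUPROFEN STADA 600 mg Zäpfchen,Ibuprofen,M01AE01
PARACETAMOL HEXAL 500 mg Tabletten,Paracetamol,N02BE01
ARILIN 500 Filmtabletten,Metronidazol,P01AB01
TELMISARTAN PLUS comp 80 mg Tabletten,Telmisartan,C09DA07
TELMISARTAN AL 80 mg Tabletten,Telmisartan,C09CA07
NATRIUMCHLORID BRAUN 0.9% Infusionslösung,Natriumchlorid,B05BB11
PANTOPRAZOL AL 40 mg Tabletten,Pantoprazol,A02BC02
METAMIZOL HEXAL 500 mg Tropfen,Metamizol,N02BB02
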