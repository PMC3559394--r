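id,code,sex,age_years,age_class,rearing,mother_id,group_id
Opala,OP,F,16,adult,orphan,,G1
Semendwa,SW,F,14,adult,orphan,,G1
Bandundu,BD,F,14,adult,orphan,,G1
Kalina,KL,F,13,adult,orphan,,G1
Salonga,SL,F,13,adult,orphan,,G1
Kisantu,KS,F,12,adult,orphan,,G1
Lisala,LS,F,10,adolescent,orphan,,G1
Katako,KT,F,7,juvenile,orphan,,G1
Elikia,EK,F,6,juvenile,mother_reared,Semendwa,G1
Masisi,MS,F,5,juvenile,orphan,,G1
Waka,WK,F,5,juvenile,orphan,,G1
Malaika,ML,F,4,juvenile,mother_reared,Kalina,G1
Manono,MN,M,17,adult,orphan,,G1
Kikwit,KW,M,13,adult,orphan,,G1
Fizi,FZ,M,12,adult,orphan,,G1
Matadi,MA,M,11,adolescent,orphan,,G1
Dilolo,DL,M,10,adolescent,orphan,,G1
Kasongo,KG,M,9,adolescent,orphan,,G1
Mabali,MB,M,8,adolescent,orphan,,G1
Pole,PO,M,6,juvenile,mother_reared,Opala,G1
Wongolo,WO,M,3,juvenile,mother_reared,Bandundu,G1
Makasi,MKS,M,1,infant,mother_reared,Semendwa,G1
Bolingo,BLG,M,1,infant,mother_reared,Kalina,G1
Kimia,KIM,F,1,infant,mother_reared,Salonga,G1
Liyaka,LYK,F,1,infant,mother_reared,Kisantu,G1
Maya,MY,F,18,adult,orphan,,G2
Tshilomba,TL,F,20,adult,orphan,,G2
Isiro,IS,F,13,adult,orphan,,G2
Likasi,LI,F,10,adolescent,orphan,,G2
Sake,SK,F,6,juvenile,orphan,,G2
Keza,KZ,M,20,adult,orphan,,G2
Makali,MK,M,20,adult,orphan,,G2
Max,MX,M,25,adult,orphan,,G2
Lomami,LM,M,12,adult,orphan,,G2
Mbandaka,MB,M,9,adolescent,orphan,,G2
Bili,BL,M,10,adolescent,orphan,,G2
Ilebo,IB,M,9,adolescent,orphan,,G2
Yolo,YL,M,7,adolescent,orphan,,G2
Bisengo,BS,M,6,juvenile,mother_reared,Maya,G2
Moyi,MO,M,4,juvenile,mother_reared,Tshilomba,G2
Mayele,MYL,M,1,infant,mother_reared,Maya,G2
Sanza,SNZ,M,1,infant,mother_reared,Tshilomba,G2
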