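# Catalogue of common, commercially available restriction endonucleases.
# Curated by the package authors from public supplier listings (prototype
# names; recognition sequences in IUPAC notation, one record per line).
# Columns: name <TAB> recognition
name	recognition
AatII	GACGTC
AccI	GTMKAC
AciI	CCGC
AclI	AACGTT
AfeI	AGCGCT
AflII	CTTAAG
AflIII	ACRYGT
AgeI	ACCGGT
AhdI	GACNNNNNGTC
AluI	AGCT
AlwNI	CAGNNNCTG
ApaI	GGGCCC
ApaLI	GTGCAC
ApoI	RAATTY
AscI	GGCGCGCC
AseI	ATTAAT
AvaI	CYCGRG
AvaII	GGWCC
AvrII	CCTAGG
BamHI	GGATCC
BanI	GGYRCC
BanII	GRGCYC
BclI	TGATCA
BglI	GCCNNNNNGGC
BglII	AGATCT
BlpI	GCTNAGC
BmtI	GCTAGC
BsaAI	YACGTR
BsaBI	GATNNNNATC
BsaHI	GRCGYC
BsaI	GGTCTC
BsiEI	CGRYCG
BsiWI	CGTACG
BsmBI	CGTCTC
BspEI	TCCGGA
BspHI	TCATGA
BsrGI	TGTACA
BssHII	GCGCGC
BstBI	TTCGAA
BstEII	GGTNACC
BstNI	CCWGG
BstXI	CCANNNNNNTGG
BstZ17I	GTATAC
Bsu36I	CCTNAGG
BtgI	CCRYGG
ClaI	ATCGAT
DdeI	CTNAG
DpnI	GATC
DraI	TTTAAA
DraIII	CACNNNGTG
DrdI	GACNNNNNNGTC
EaeI	YGGCCR
EagI	CGGCCG
EarI	CTCTTC
EcoNI	CCTNNNNNAGG
EcoO109I	RGGNCCY
EcoRI	GAATTC
EcoRV	GATATC
FseI	GGCCGGCC
FspI	TGCGCA
HaeII	RGCGCY
HaeIII	GGCC
HhaI	GCGC
HincII	GTYRAC
HindIII	AAGCTT
HinfI	GANTC
HpaI	GTTAAC
HpaII	CCGG
HphI	GGTGA
KasI	GGCGCC
KpnI	GGTACC
MfeI	CAATTG
MluI	ACGCGT
MscI	TGGCCA
MseI	TTAA
MslI	CAYNNNNRTG
MspA1I	CMGCKG
NaeI	GCCGGC
NcoI	CCATGG
NdeI	CATATG
NheI	GCTAGC
NlaIII	CATG
NotI	GCGGCCGC
NruI	TCGCGA
NsiI	ATGCAT
NspI	RCATGY
PacI	TTAATTAA
PciI	ACATGT
PflMI	CCANNNNNTGG
PmeI	GTTTAAAC
PmlI	CACGTG
PpuMI	RGGWCCY
PshAI	GACNNNNGTC
PsiI	TTATAA
PspOMI	GGGCCC
PstI	CTGCAG
PvuI	CGATCG
PvuII	CAGCTG
RsaI	GTAC
SacI	GAGCTC
SacII	CCGCGG
SalI	GTCGAC
SapI	GCTCTTC
Sau3AI	GATC
SbfI	CCTGCAGG
ScaI	AGTACT
SfcI	CTRYAG
SfiI	GGCCNNNNNGGCC
SfoI	GGCGCC
SgrAI	CRCCGGYG
SmaI	CCCGGG
SnaBI	TACGTA
SpeI	ACTAGT
SphI	GCATGC
SspI	AATATT
StuI	AGGCCT
StyI	CCWWGG
SwaI	ATTTAAAT
TaqI	TCGA
TfiI	GAWTC
TseI	GCWGC
Tth111I	GACNNNGTC
XbaI	TCTAGA
XhoI	CTCGAG
XmaI	CCCGGG
XmnI	GAANNNNTTC
ZraI	GACGTC
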