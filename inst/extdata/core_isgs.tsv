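gene	alias	functional_category	mammal_only	members
B2M	NA	antigen_presentation	FALSE	NA
ERAP1	NA	antigen_presentation	FALSE	NA
HLA	NA	antigen_presentation	FALSE	HLA-A;HLA-B;HLA-C;HLA-E;HLA-F;HLA-G
NLRC5	NA	antigen_presentation	FALSE	NA
PSMA5	NA	antigen_presentation	TRUE	NA
PSMB8	NA	antigen_presentation	TRUE	NA
PSMB9	NA	antigen_presentation	TRUE	NA
PSMB10	NA	antigen_presentation	TRUE	NA
PSME1	NA	antigen_presentation	TRUE	NA
PSME2	NA	antigen_presentation	TRUE	NA
RFX5	NA	antigen_presentation	FALSE	NA
TAP1	NA	antigen_presentation	FALSE	NA
TAP2	NA	antigen_presentation	FALSE	NA
TAPBP	NA	antigen_presentation	FALSE	NA
TAPBPL	NA	antigen_presentation	FALSE	NA
ADAR	NA	antiviral	FALSE	NA
APOL	NA	antiviral	TRUE	APOL1;APOL2;APOL3;APOL4
C19orf66	IRAV	antiviral	TRUE	NA
IFIT2	NA	antiviral	FALSE	NA
IFIT3	NA	antiviral	FALSE	NA
ISG15	NA	antiviral	TRUE	NA
ISG20	NA	antiviral	TRUE	NA
MORC3	NA	antiviral	FALSE	NA
MOV10	NA	antiviral	FALSE	NA
MX1	NA	antiviral	FALSE	NA
OAS1	NA	antiviral	FALSE	NA
PARP12	NA	antiviral	FALSE	NA
PKR	EIF2AK2	antiviral	FALSE	NA
PML	NA	antiviral	FALSE	NA
RSAD2	viperin	antiviral	FALSE	NA
SAT1	NA	antiviral	FALSE	NA
SCOTIN	SHISA5	antiviral	FALSE	NA
ZAP	ZC3HAV1	antiviral	FALSE	NA
DTX3L	NA	ubiquitin_protein_modification	FALSE	NA
HERC6	NA	ubiquitin_protein_modification	TRUE	NA
N4BP1	NA	ubiquitin_protein_modification	FALSE	NA
NUB1	NA	ubiquitin_protein_modification	FALSE	NA
PARP9	NA	ubiquitin_protein_modification	FALSE	NA
RBCK1	NA	ubiquitin_protein_modification	TRUE	NA
RNF19B	NA	ubiquitin_protein_modification	FALSE	NA
RNF213	NA	ubiquitin_protein_modification	FALSE	NA
RNF31	NA	ubiquitin_protein_modification	TRUE	NA
UBA7	NA	ubiquitin_protein_modification	TRUE	NA
UBE2L6	NA	ubiquitin_protein_modification	FALSE	NA
AZI2	NA	pamp_sensing_ifn_pathway	FALSE	NA
cGAS	MB21D1	pamp_sensing_ifn_pathway	TRUE	NA
IRF1	NA	pamp_sensing_ifn_pathway	FALSE	NA
IRF7	NA	pamp_sensing_ifn_pathway	FALSE	NA
IRF9	NA	pamp_sensing_ifn_pathway	TRUE	NA
LGP2	DHX58	pamp_sensing_ifn_pathway	FALSE	NA
MDA5	IFIH1	pamp_sensing_ifn_pathway	FALSE	NA
MYD88	NA	pamp_sensing_ifn_pathway	FALSE	NA
RIG-I	DDX58	pamp_sensing_ifn_pathway	TRUE	NA
RNF114	NA	pamp_sensing_ifn_pathway	FALSE	NA
STAT1	NA	pamp_sensing_ifn_pathway	FALSE	NA
STAT2	NA	pamp_sensing_ifn_pathway	FALSE	NA
TLR3	NA	pamp_sensing_ifn_pathway	FALSE	NA
TRIM25	NA	pamp_sensing_ifn_pathway	FALSE	NA
CD274	NA	ifn_suppression	FALSE	NA
IFI35	NA	ifn_suppression	FALSE	NA
NMI	NA	ifn_suppression	FALSE	NA
PARP14	NA	ifn_suppression	FALSE	NA
SOCS1	NA	ifn_suppression	FALSE	NA
TRAFD1	NA	ifn_suppression	FALSE	NA
TRIM21	NA	ifn_suppression	FALSE	NA
USP18	NA	ifn_suppression	FALSE	NA
USP25	NA	ifn_suppression	FALSE	NA
CASP8	NA	cell_signalling_apoptosis	TRUE	NA
CD47	NA	cell_signalling_apoptosis	FALSE	NA
IL15RA	NA	cell_signalling_apoptosis	FALSE	NA
LGALS9	NA	cell_signalling_apoptosis	TRUE	NA
RICTOR	NA	cell_signalling_apoptosis	FALSE	NA
TRAIL	TNFSF10	cell_signalling_apoptosis	FALSE	NA
C2	NA	miscellaneous	TRUE	NA
CMPK2	NA	miscellaneous	FALSE	NA
CMTR1	NA	miscellaneous	FALSE	NA
DNAJA1	NA	miscellaneous	TRUE	NA
DNAJC13	NA	miscellaneous	FALSE	NA
EHD4	NA	miscellaneous	TRUE	NA
FAM46A	NA	miscellaneous	FALSE	NA
FMR1	NA	miscellaneous	FALSE	NA
PNPT1	NA	miscellaneous	FALSE	NA
SERTAD1	NA	miscellaneous	TRUE	NA
SLC25A28	NA	miscellaneous	TRUE	NA
SP110	NA	miscellaneous	TRUE	NA
TDRD7	NA	miscellaneous	TRUE	NA
WARS	NA	miscellaneous	TRUE	NA
XAF1	NA	miscellaneous	TRUE	NA
ZCCHC2	NA	miscellaneous	FALSE	NA
ZNFX1	NA	miscellaneous	FALSE	NA
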