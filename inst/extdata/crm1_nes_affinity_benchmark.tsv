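name	class	start	end	sequence	phi_registry	kd_nM	binder	consensus_fit	note
MVM NS2	1a	77	93	STVDEMTKKFGTLTIHD	3,6,10,13,15	2	TRUE	TRUE	NA
super PKI	1a	34	49	NLNELALKLAGLDINK	2,5,9,12,14	4	TRUE	TRUE	engineered
PKI	1a	34	49	NSNELALKLAGLDINK	5,9,12,14	34	TRUE	TRUE	NA
ADAR1	1a	121	137	RGVDCLSSHFQELSIYQ	3,6,10,13,15	69	TRUE	TRUE	NA
MEK1	1a	28	44	TNLEALQKKLEELELDE	3,6,10,13,15	70	TRUE	TRUE	NA
Pax	1a	264	280	RELDELMASLSDFKFMA	3,6,10,13,15	700	TRUE	TRUE	NA
CPEB4-R	1a	395	379	RMIDILSSELSHMDFTR	3,6,10,13,15	710	TRUE	TRUE	engineered
NPMmutA	1a	278	298	MTDQEAIQDLCLAVEEVSLRK	7,10,14,17,19	790	TRUE	TRUE	NA
HDAC5	1a	1081	1095	EAETVSAMALLSVG	4,8,11,13	1600	TRUE	TRUE	NA
p73	1a	364	382	NFEILMKLKESLELMELVP	5,8,12,15,17	2000	TRUE	TRUE	NA
hRio2-R	1a	405	389	GKIEELAQNFETMEFSR	3,6,10,13,15	2600	TRUE	TRUE	engineered
Strada	1a	413	427	GIFGLVTNLEELEVD	2,5,9,12,14	10300	TRUE	TRUE	NA
FMRP-1b	1b	NA	NA	YLKEVDQLRALERLQID	5,8,11,14,16	3000	TRUE	TRUE	engineered
SNUPN	1c	1	20	MEELSQALASSFSVSQDLNS	1,4,8,12,14	12500	TRUE	TRUE	NA
HPV E7	1c	73	91	HVDIRTLEDLLMGTLGIVC	4,7,11,15,17	34000	TRUE	TRUE	NA
HIV Rev	2	73	85	LQLPPLERLTLDC	NA	1180	TRUE	TRUE	ambiguous registry annotation
FMRP	2	424	438	LKEVDQLRLERLQID	4,7,9,12,14	2000	TRUE	TRUE	NA
SMAD4	2	134	149	ERVVSPGIDLSGLTLQ	8,10,13,15	4600	TRUE	TRUE	NA
mDia2	3	1157	1171	SVPEVEALLARLRAL	5,8,12,15	1600	TRUE	TRUE	NA
CDC7	3	456	473	QDLRKLCERLRGMDSSTP	3,6,10,13	20000	TRUE	TRUE	NA
X11L2	4	55	72	SSLQELVQQFEALPGDLV	3,6,10,13,17	1500	TRUE	TRUE	NA
CPEB4	1a-R	379	395	RTFDMHSLESSLIDIMR	3,5,8,12,15	800	TRUE	TRUE	NA
hRio2	1a-R	389	405	RSFEMTEFNQALEEIKG	3,5,8,12,15	2800	TRUE	TRUE	NA
PKImut1 (I47A)	-	34	49	NSNELALKLAGLDANK	5,9,12	150000	TRUE	TRUE	engineered mutant
PKImut2 (L42A/L45A)	-	34	49	NSNELALKAAGADINK	5,14	900000	TRUE	TRUE	engineered mutant
APC	1a	163	174	AQLQNLTKRIDSLPL	3,6,10,13,15	NA	FALSE	FALSE	NA
Cyclin D1	1a	281	295	VDLACTPTDVRDVDI	3,6,10,13,15	NA	FALSE	TRUE	unpublished
APRIL	1b	106	120	LEPLKKLECLKSLDL	4,7,10,13,15	NA	FALSE	TRUE	NA
hTERT	1c	965	982	KAGRNMRRKLFGVLRLKC	6,10,14,16	NA	FALSE	TRUE	unpublished
DcpS	1c	136	150	TEKHLQKYLRQDLRL	5,9,13,15	NA	FALSE	TRUE	NA
Cdk5	2	133	147	LINRNGELKLADFGL	8,10,13,15	NA	FALSE	TRUE	NA
FGF1	2	138	152	THYGQKAILFLPLPV	8,10,13,15	NA	FALSE	FALSE	NA
COMMD1	3	171	185	ILKTLSEVEESISTL	5,8,12,15	NA	FALSE	TRUE	NA
DEAF1	1a-R	452	469	SWLYLEEMVNSLLNTAQQ	3,5,8,12	NA	FALSE	TRUE	NA
SGN5	1a-R	221	238	YALEVSYFKSSLDRKLL	3,5,8,12	NA	FALSE	TRUE	NA
COMMD1-2	1a-R	164	181	DEVKVNQILKTLSEVEES	3,5,8,12,15	NA	FALSE	FALSE	NA
ELF3	1a-R	111	126	RLVFGPLGDQLHAQLR	2,4,7,11	NA	FALSE	FALSE	NA
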