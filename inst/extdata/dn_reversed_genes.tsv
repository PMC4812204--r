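drug	direction	gene
Piperlongumine	decrease	CLEC5A
Piperlongumine	decrease	TNFAIP6
Piperlongumine	decrease	FCGR1B
Piperlongumine	decrease	C3
Piperlongumine	decrease	NEIL3
Piperlongumine	decrease	RNASE6
Piperlongumine	decrease	C3AR1
Piperlongumine	decrease	SAMSN1
Piperlongumine	decrease	CAPG
Piperlongumine	decrease	CD86
Piperlongumine	decrease	TREM1
Piperlongumine	decrease	IRF8
Piperlongumine	decrease	EVI2A
Piperlongumine	decrease	PBK
Piperlongumine	decrease	FCGR2A
Piperlongumine	decrease	RGS13
Piperlongumine	decrease	KCNN4
Piperlongumine	decrease	GPR183
Piperlongumine	decrease	TLR2
Piperlongumine	decrease	GINS2
Piperlongumine	decrease	CLEC7A
Piperlongumine	decrease	RRM2
Piperlongumine	decrease	RGS1
Piperlongumine	decrease	CD300A
Piperlongumine	decrease	CD14
Piperlongumine	decrease	CTSC
Piperlongumine	decrease	TMEM158
Piperlongumine	decrease	CDCA3
Piperlongumine	decrease	NCF2
Piperlongumine	decrease	SYK
Piperlongumine	decrease	IL1B
Piperlongumine	decrease	GINS1
Piperlongumine	decrease	SLC43A3
Piperlongumine	decrease	PSRC1
Piperlongumine	decrease	MYC
Piperlongumine	decrease	FILIP1L
Piperlongumine	decrease	MYO1F
Piperlongumine	decrease	PLAUR
Piperlongumine	decrease	PFKP
Piperlongumine	decrease	CCR1
Piperlongumine	decrease	HELLS
Piperlongumine	decrease	PLAU
Piperlongumine	decrease	PTPRE
Piperlongumine	decrease	MNDA
Piperlongumine	decrease	TNFAIP8
Piperlongumine	decrease	MAD2L1
Piperlongumine	decrease	CYP1B1
Piperlongumine	decrease	RASSF2
Piperlongumine	decrease	GALNT7
Piperlongumine	decrease	ECT2
Piperlongumine	decrease	CD300C
Piperlongumine	decrease	CDC45
Piperlongumine	increase	HPS5
Piperlongumine	increase	EAF2
Piperlongumine	increase	RND1
15d-PGJ2	decrease	MLPH
15d-PGJ2	decrease	CXCL6
15d-PGJ2	decrease	TOP2A
15d-PGJ2	decrease	LPAR1
15d-PGJ2	decrease	GPR39
15d-PGJ2	decrease	DLGAP5
15d-PGJ2	decrease	HMGA2
15d-PGJ2	decrease	SCG5
15d-PGJ2	decrease	CXCL1
15d-PGJ2	decrease	PTX3
15d-PGJ2	decrease	INHBA
15d-PGJ2	decrease	TNFRSF11A
15d-PGJ2	decrease	COL5A2
15d-PGJ2	decrease	TENM4
15d-PGJ2	decrease	ASPM
15d-PGJ2	decrease	KIF18B
15d-PGJ2	decrease	CENPF
15d-PGJ2	decrease	KIF20A
15d-PGJ2	decrease	IL33
15d-PGJ2	decrease	SYTL2
15d-PGJ2	decrease	CCNB2
15d-PGJ2	decrease	CCNA1
15d-PGJ2	decrease	HJURP
15d-PGJ2	decrease	CDC20
15d-PGJ2	decrease	CDH11
15d-PGJ2	decrease	LMNB1
15d-PGJ2	decrease	NCAPH
15d-PGJ2	decrease	MKI67
15d-PGJ2	decrease	CDCA3
15d-PGJ2	decrease	FST
15d-PGJ2	decrease	TTK
15d-PGJ2	decrease	NDP
15d-PGJ2	decrease	GINS1
15d-PGJ2	decrease	MTCL1
15d-PGJ2	decrease	PSRC1
15d-PGJ2	decrease	NEK2
15d-PGJ2	decrease	HAS2
15d-PGJ2	decrease	CDCA8
15d-PGJ2	decrease	NPM3
15d-PGJ2	decrease	ETV1
15d-PGJ2	decrease	KIF2C
15d-PGJ2	decrease	FAM110B
15d-PGJ2	decrease	PRSS23
15d-PGJ2	decrease	CDK1
15d-PGJ2	decrease	PLAU
15d-PGJ2	decrease	MALL
15d-PGJ2	decrease	P2RY6
15d-PGJ2	decrease	AURKB
15d-PGJ2	decrease	BNC2
15d-PGJ2	decrease	FJX1
15d-PGJ2	decrease	CCNB1
15d-PGJ2	decrease	TROAP
15d-PGJ2	decrease	IGSF3
15d-PGJ2	decrease	CYP1B1
15d-PGJ2	decrease	ECT2
15d-PGJ2	decrease	TK1
15d-PGJ2	decrease	IRS1
15d-PGJ2	increase	PRKCE
15d-PGJ2	increase	SLC16A10
15d-PGJ2	increase	ERVMER34-1
15d-PGJ2	increase	EAF2
15d-PGJ2	increase	RND1
15d-PGJ2	increase	EGF
15d-PGJ2	increase	ZNF804A
15d-PGJ2	increase	SERPINI2
Vorinostat	decrease	CLEC5A
Vorinostat	decrease	PLA2G7
Vorinostat	decrease	CTSG
Vorinostat	decrease	FCGR1A
Vorinostat	decrease	FCGR1B
Vorinostat	decrease	VCAN
Vorinostat	decrease	LAIR1
Vorinostat	decrease	BCAT1
Vorinostat	decrease	HP
Vorinostat	decrease	PTAFR
Vorinostat	decrease	C3AR1
Vorinostat	decrease	ADORA3
Vorinostat	decrease	LILRB4
Vorinostat	decrease	HGF
Vorinostat	decrease	IGSF6
Vorinostat	decrease	CCR2
Vorinostat	decrease	NCF4
Vorinostat	decrease	MS4A6A
Vorinostat	decrease	CD33
Vorinostat	decrease	MMP9
Vorinostat	decrease	GNA15
Vorinostat	decrease	EVI2A
Vorinostat	decrease	TLR1
Vorinostat	decrease	ATP8B4
Vorinostat	decrease	CACNA2D3
Vorinostat	decrease	LILRB1
Vorinostat	decrease	KCNN4
Vorinostat	decrease	GPR183
Vorinostat	decrease	ANXA3
Vorinostat	decrease	TLR2
Vorinostat	decrease	CLEC7A
Vorinostat	decrease	RRM2
Vorinostat	decrease	RGS1
Vorinostat	decrease	LMNB1
Vorinostat	decrease	NINJ2
Vorinostat	decrease	CD300A
Vorinostat	decrease	CSF2RA
Vorinostat	decrease	NCAPH
Vorinostat	decrease	CD14
Vorinostat	decrease	INHBE
Vorinostat	decrease	LILRA2
Vorinostat	decrease	SIGLEC9
Vorinostat	decrease	LAT2
Vorinostat	decrease	SYK
Vorinostat	decrease	SLC38A1
Vorinostat	decrease	SLC43A3
Vorinostat	decrease	MYC
Vorinostat	decrease	GLIPR1
Vorinostat	decrease	PTENP1
Vorinostat	decrease	MYO1F
Vorinostat	decrease	PSTPIP1
Vorinostat	decrease	PLAUR
Vorinostat	decrease	CCR1
Vorinostat	decrease	PLAU
Vorinostat	decrease	DOK3
Vorinostat	decrease	SELPLG
Vorinostat	decrease	SASH3
Vorinostat	decrease	P2RY6
Vorinostat	decrease	VAV1
Vorinostat	decrease	PTPRE
Vorinostat	decrease	MNDA
Vorinostat	decrease	SPI1
Vorinostat	decrease	DEF6
Vorinostat	decrease	CYBRD1
Vorinostat	decrease	CXorf21
Vorinostat	decrease	CYP1B1
Vorinostat	decrease	RASSF2
Vorinostat	decrease	DOK2
Vorinostat	increase	ACOX2
Vorinostat	increase	EXPH5
Vorinostat	increase	PRKAR2B
Vorinostat	increase	GDPD3
Vorinostat	increase	MLXIPL
Vorinostat	increase	RND1
Vorinostat	increase	CTSV
Trichostatin A	decrease	CLEC5A
Trichostatin A	decrease	FCGR1B
Trichostatin A	decrease	VCAN
Trichostatin A	decrease	LAIR1
Trichostatin A	decrease	RNASE6
Trichostatin A	decrease	C3AR1
Trichostatin A	decrease	HGF
Trichostatin A	decrease	IGSF6
Trichostatin A	decrease	NCF4
Trichostatin A	decrease	MS4A6A
Trichostatin A	decrease	SLC7A11
Trichostatin A	decrease	EVI2A
Trichostatin A	decrease	KIF20A
Trichostatin A	decrease	ATP8B4
Trichostatin A	decrease	CACNA2D3
Trichostatin A	decrease	RGS13
Trichostatin A	decrease	KCNN4
Trichostatin A	decrease	GPR183
Trichostatin A	decrease	ANXA3
Trichostatin A	decrease	CLEC7A
Trichostatin A	decrease	RRM2
Trichostatin A	decrease	RGS1
Trichostatin A	decrease	LMNB1
Trichostatin A	decrease	CD300A
Trichostatin A	decrease	CD14
Trichostatin A	decrease	INHBE
Trichostatin A	decrease	PYCARD
Trichostatin A	decrease	LILRA2
Trichostatin A	decrease	SYK
Trichostatin A	decrease	SLC38A1
Trichostatin A	decrease	SLC43A3
Trichostatin A	decrease	PIK3CG
Trichostatin A	decrease	MYC
Trichostatin A	decrease	FILIP1L
Trichostatin A	decrease	PSTPIP1
Trichostatin A	decrease	PLAUR
Trichostatin A	decrease	FOXM1
Trichostatin A	decrease	PLAU
Trichostatin A	decrease	SASH3
Trichostatin A	decrease	P2RY6
Trichostatin A	decrease	VAV1
Trichostatin A	decrease	MNDA
Trichostatin A	decrease	SPI1
Trichostatin A	decrease	CSF3R
Trichostatin A	decrease	CYBRD1
Trichostatin A	decrease	CXorf21
Trichostatin A	decrease	MICAL1
Trichostatin A	decrease	CYP1B1
Trichostatin A	decrease	RCC1
Trichostatin A	decrease	P2RX1
Trichostatin A	decrease	ARRB2
Trichostatin A	decrease	RASSF2
Trichostatin A	decrease	GALNT7
Trichostatin A	decrease	DOK2
Trichostatin A	decrease	FAM129A
Trichostatin A	increase	PRKAR2B
Trichostatin A	increase	CTNNBIP1
Trichostatin A	increase	RND1
Trichostatin A	increase	CTSV
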