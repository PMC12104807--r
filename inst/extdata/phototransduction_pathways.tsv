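family	pathway	ko	gene
fly:K00910	fly	K00910	GRK
fly:K02183	fly	K02183	CALM
fly:K02677	fly	K02677	PRKCA
fly:K04515	fly	K04515	CaMKII
fly:K04547	fly	K04547	GNG13
fly:K04634	fly	K04634	GNAQ
fly:K04958	fly	K04958	IP3R
fly:K04967	fly	K04967	TRPC4
fly:K05692	fly	K05692	ACTB_G1
fly:K05858	fly	K05858	PLCB
fly:K07972	fly	K07972	GNBh
fly:K08834	fly	K08834	MYO3
fly:K13802	fly	K13802	Rh1
fly:K13803	fly	K13803	TRPL
fly:K13804	fly	K13804	INAD
fly:K13805	fly	K13805	ARR2
fly:K13806	fly	K13806	DAGL
fly:K13807	fly	K13807	PPEF/PPP7C
vertebrate:K00909	vertebrate	K00909	GRK1
vertebrate:K02183	vertebrate	K02183	CALM
vertebrate:K04250	vertebrate	K04250	RHO/OPN2
vertebrate:K04536	vertebrate	K04536	GNB1
vertebrate:K04548	vertebrate	K04548	GNGT1
vertebrate:K04631	vertebrate	K04631	GNAT1
vertebrate:K04948	vertebrate	K04948	CNGA1
vertebrate:K04952	vertebrate	K04952	CNGB1
vertebrate:K08328	vertebrate	K08328	GUCA1
vertebrate:K08718	vertebrate	K08718	PDE6A
vertebrate:K12321	vertebrate	K12321	GUCY2D_E
vertebrate:K12322	vertebrate	K12322	GUCY2F
vertebrate:K13749	vertebrate	K13749	SLC24A1/NCKX1
vertebrate:K13756	vertebrate	K13756	PDE6B
vertebrate:K13759	vertebrate	K13759	PDE6G
vertebrate:K13764	vertebrate	K13764	RCVRN
vertebrate:K13765	vertebrate	K13765	RGS9
vertebrate:K19627	vertebrate	K19627	SAG
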