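family	Xenacoelomorpha	Chordata	Protostomia
fly:K00910	1	1	1
fly:K02183	1	1	1
fly:K02677	1	1	1
fly:K04515	1	1	1
fly:K04547	1	1	1
fly:K04634	1	1	1
fly:K04958	1	1	1
fly:K04967	1	1	1
fly:K05692	1	1	1
fly:K05858	1	1	1
fly:K07972	0	0	1
fly:K08834	1	1	1
fly:K13802	0	0	1
fly:K13803	1	0	1
fly:K13804	0	0	1
fly:K13805	0	0	1
fly:K13806	1	1	1
fly:K13807	1	1	1
vertebrate:K00909	0	1	0
vertebrate:K02183	1	1	1
vertebrate:K04250	1	1	1
vertebrate:K04536	1	1	1
vertebrate:K04548	0	1	0
vertebrate:K04631	0	1	0
vertebrate:K04948	0	1	1
vertebrate:K04952	0	1	1
vertebrate:K08328	1	1	1
vertebrate:K08718	0	1	0
vertebrate:K12321	0	1	0
vertebrate:K12322	0	1	1
vertebrate:K13749	1	1	0
vertebrate:K13756	0	1	0
vertebrate:K13759	0	1	0
vertebrate:K13764	0	1	0
vertebrate:K13765	0	1	1
vertebrate:K19627	0	1	0
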