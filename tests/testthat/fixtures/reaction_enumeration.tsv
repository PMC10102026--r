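module	reaction	compartments	directions	count
import	Impa + Impb <-> Impa.Impb	cytoplasm,nucleus	2	4
import	Impb + RanGTP <-> Impb.RanGTP	cytoplasm,nucleus	2	4
import	Impa.Impb + RanGTP -> Impb.RanGTP + Impa	cytoplasm,nucleus	1	2
cas	CAS + RanGTP <-> CAS.RanGTP	cytoplasm,nucleus	2	4
cas	CAS.RanGTP + Impa <-> CAS.RanGTP.Impa	cytoplasm,nucleus	2	4
cas	CAS + Impa <-> CAS.Impa	cytoplasm,nucleus	2	4
cas	CAS.Impa + RanGTP <-> CAS.RanGTP.Impa	cytoplasm,nucleus	2	4
export	CRM1 + RanGTP <-> CRM1.RanGTP	cytoplasm,nucleus	2	4
export	CRM1 + RanBP3 <-> CRM1.RanBP3	cytoplasm,nucleus	2	4
export	CRM1.RanBP3 + RanGTP <-> CRM1.RanBP3.RanGTP	cytoplasm,nucleus	2	4
rancycle	NTF2 + RanGDP <-> NTF2.RanGDP	cytoplasm,nucleus	2	4
rancycle	RanGDP + RCC1 -> RanGTP + RCC1	nucleus	1	1
rancycle	RanGTP + RanGAP -> RanGDP + RanGAP	cytoplasm	1	1
rancycle	RanBP1 + RanGTP <-> RanBP1.RanGTP	cytoplasm	2	2
rancycle	RanBP1.RanGTP + RanGAP -> RanBP1 + RanGDP + RanGAP	cytoplasm	1	1
strip	Impb.RanGTP + RanBP1 -> Impb + RanBP1.RanGTP	cytoplasm	1	1
strip	CAS.RanGTP + RanBP1 -> CAS + RanBP1.RanGTP	cytoplasm	1	1
strip	CAS.RanGTP.Impa + RanBP1 -> CAS + Impa + RanBP1.RanGTP	cytoplasm	1	1
strip	CRM1.RanGTP + RanBP1 -> CRM1 + RanBP1.RanGTP	cytoplasm	1	1
strip	CRM1.RanBP3.RanGTP + RanBP1 -> CRM1 + RanBP3 + RanBP1.RanGTP	cytoplasm	1	1
pore	NTF2 translocation cy<->pore<->nu	pore	4	4
pore	NTF2.RanGDP translocation	pore	4	4
pore	RanBP3 translocation	pore	4	4
pore	Impb translocation	pore	4	4
pore	Impa.Impb translocation	pore	4	4
pore	Impb.RanGTP translocation	pore	4	4
pore	CAS translocation	pore	4	4
pore	CAS.RanGTP translocation	pore	4	4
pore	CAS.RanGTP.Impa translocation	pore	4	4
pore	CAS.Impa translocation	pore	4	4
pore	CRM1 translocation	pore	4	4
pore	CRM1.RanGTP translocation	pore	4	4
pore	CRM1.RanBP3 translocation	pore	4	4
pore	CRM1.RanBP3.RanGTP translocation	pore	4	4
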