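cdr3_aa	chain	v_gene	j_gene	epitope	pathogen	species
CAEWFPPTWSGSEFF	TRB	TRBV21	TRBJ2-2	ISINAMPHF	EBV	HomoSapiens
CATNTNWDHTLSF	TRB			FWCYQIHDL	EBV	HomoSapiens
CAREDQPQFCF	TRB		TRBJ2-3	IKIFWNAGD	EBV	HomoSapiens
CADWAYEWEAAWSDWF	TRB			IMNRAELHP	EBV	HomoSapiens
CAGLPEQGDGQLRHVF	TRB	TRBV3	TRBJ1-1	SVAIGNLKH	EBV	HomoSapiens
CACQISKFINKYF	TRB			DGPGVYFSQ	EBV	HomoSapiens
CANLNPNVQDYPF	TRB		TRBJ2-1	FYNYSHCIG	EBV	HomoSapiens
CAKAMPDSTLEF	TRB		TRBJ1-2	SWDATADHK	EBV	HomoSapiens
CANTIITQLVGF	TRB	TRBV4		GWDMVFEYS	EBV	HomoSapiens
CATPDHHRAMCF	TRB		TRBJ1-1	KDLRYVTCR	EBV	HomoSapiens
CAKETTNALYSFPF	TRB			SEIHKVAEM	EBV	HomoSapiens
CAWTVFFKMQGSWDGF	TRA			WVKACDEQD	EBV	HomoSapiens
CARHQHICSVFTF	TRB		TRBJ1-6	GYADPVVVG	EBV	HomoSapiens
CARCCEHFADYAVSFF	TRB	TRBV6	TRBJ2-2	HPNCDCEPD	EBV	HomoSapiens
CALCMDLAAYCSWF	TRB		TRBJ1-5	WCFMFVTVD	EBV	HomoSapiens
CAKLDMNGCLRWYF	TRB			IWDCFVCEP	CMV	HomoSapiens
CAHDYCHMIQNKQF	TRB			VCDTDVMSW	CMV	HomoSapiens
CAMPSGGESDPWYFF	TRB			YWKRQMQVI	CMV	HomoSapiens
CAFQDQVPWPGNF	TRB		TRBJ1-2	TNQSSAHNY	CMV	HomoSapiens
CATPCDIQTSRF	TRB		TRBJ2-6	CMGSWVRRT	CMV	HomoSapiens
CASSWMTTKNAGTCLCF	TRB		TRBJ1-4	SQHMDIYEQ	CMV	HomoSapiens
CAGRGFEKQVWHCRITF	TRB			YHNFLYWMH	CMV	HomoSapiens
CAYQENYDWAHSHF	TRB		TRBJ2-1	NLNHTKSIQ	CMV	HomoSapiens
CAAVADFIEHCHKF	TRB			GFSAHAGTR	CMV	HomoSapiens
CARTQRTYECRF	TRA	TRAV30	TRAJ32	AWVISSHFS	CMV	HomoSapiens
CAILMNFQLTWGLERF	TRA			EWENKHYRP	CMV	HomoSapiens
CACQLVCFGNF	TRB		TRBJ2-5	DESPVTITN	CMV	HomoSapiens
CAFHAIEPYRIAF	TRB	TRBV6		ICFCMDNVV	CMV	HomoSapiens
CAKRFGKWNNQWGF	TRB	TRBV17	TRBJ2-3	YQCKPENKI	CMV	HomoSapiens
CAVPQDRYHRF	TRB		TRBJ1-6	YGTDVFNCG	CMV	HomoSapiens
CAPHSMDFYWEDF	TRB		TRBJ2-4	NAIHVAEKT	SARS-CoV-2	HomoSapiens
CAYIAERSGTLNF	TRB		TRBJ2-4	LYTCNEVRE	SARS-CoV-2	HomoSapiens
CARKPMEIRCF	TRB			CLHYHTVHW	SARS-CoV-2	HomoSapiens
CAWCWCVYSFAITGF	TRB	TRBV9		NQSEYSYVE	SARS-CoV-2	HomoSapiens
CAMGRQGKMDWRDHIPF	TRB	TRBV13	TRBJ1-3	MEQHHVLCM	SARS-CoV-2	HomoSapiens
CAVHMYMHTWF	TRB	TRBV7	TRBJ1-1	VYGAWTAKI	SARS-CoV-2	HomoSapiens
CAYIECVHWHMCF	TRB	TRBV23	TRBJ1-2	IAITMINLL	SARS-CoV-2	HomoSapiens
CAHETMIDFFNLNGQF	TRA			CCHMPTRSG	SARS-CoV-2	HomoSapiens
CAKAVSPVPMIGF	TRB			GPANLFKEW	SARS-CoV-2	HomoSapiens
CAPRCFEEVAVIWF	TRB	TRBV19		YVGPAQKNH	SARS-CoV-2	HomoSapiens
CASMYHFGYGF	TRB	TRBV6		TGCFDIQID	InfluenzaA	HomoSapiens
CASTECNSDIWF	TRB			PWDDHNTKD	InfluenzaA	HomoSapiens
CAGECHEMPTEANLAF	TRB		TRBJ2-3	PVVLQAMYF	InfluenzaA	HomoSapiens
CACVATVIITWMF	TRB	TRBV24		RNSERHKAE	InfluenzaA	HomoSapiens
CATLAGWCDWHLAF	TRB		TRBJ1-5	GSCALIHCS	InfluenzaA	HomoSapiens
CATIRESLVPWMWFF	TRB		TRBJ1-4	EWVAGTQRR	InfluenzaA	HomoSapiens
CAEYALSWVPAKYHF	TRA	TRAV29		ATLNEGAHM	InfluenzaA	HomoSapiens
CANWDNHIFWMLICFVF	TRB			IGVFWDFWR	InfluenzaA	HomoSapiens
CAYPAHEDYNF	TRA		TRAJ9	WSMLRKGMR	InfluenzaA	HomoSapiens
CAMPWYNDSLPYNNNNF	TRA	TRAV6	TRAJ28	VATWDPSMS	InfluenzaA	HomoSapiens
CAPVNWALKCCVF	TRB	TRBV8		LYSFDIWSG	M.tuberculosis	HomoSapiens
CAYNAVINDDF	TRA		TRAJ33	QSSPIKMYE	M.tuberculosis	HomoSapiens
CAEDRVCWQPEF	TRA			HYEICTKLC	M.tuberculosis	HomoSapiens
CARYWWIMMNDIQF	TRB			DYKGQGVMN	M.tuberculosis	HomoSapiens
CAITYKWKPSAHF	TRB			AASGNSLKE	M.tuberculosis	HomoSapiens
CANFPGQVADSGIAKQF	TRA		TRAJ20	MWKAEEWFR	EBV	MusMusculus
CAMFYLWNYHF	TRB	TRBV1		ITVQCGEFA	EBV	MusMusculus
CARAGHIANSFYHAF	TRA	TRAV25	TRAJ21	HGTNRQGYQ	EBV	MusMusculus
CAEAGLGWWWFIF	TRB	TRBV23	TRBJ2-4	KPMSGIAPE	EBV	MusMusculus
CADRCVPEFHWHLF	TRA			HQPGFHHVH	EBV	MusMusculus
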