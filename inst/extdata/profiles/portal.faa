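>portal_fam1
IQVKELIEKLASKFWATHEREEEGVLDLFDKHLNIASIQNLPETALVLLQVDVGELVKPLCAGRVEWHTT
NYDAKFLWVVFVSLDRIPFPDEVPIYSPYSNYQMTLKVVYRSFFGGRLDLRTQPNSDQDDSLLICIKLLK
DLLGWISPRFEELLLHQRFDWCPIMVTFESPTNGLLSGQDLNGTDNEEMVVSVTSNKEQTDQCIITLTVR
LGGTPNTLIGGENNSNALNFPRRGVAIVGVIDIDHTLEDQSHHMDEYDIDPISLENDLLDSGAIVWDTIK
NLLANSKVAKARGAQKRQADKKAPLIGGCATSPPKNSKSYILDTPPSTSYSWSEEVKRNTSARFRAHNGL
VVALTYKWRACVFTCDADVPVIYYPASTLPPFWPTNYGLFPLRTLYVGQDITRFSGIQNLNVKGLQYTYE
NCQSVWIVFNPGNSRYDDGQQTFLVTDYYTERSVEKMANAGGRLSLESRGIGLEYTGLGITIRLLGGTDY
PINAPIYIAPAIASFGEPPGRVFADQNYAKLDTIQSAVGGHTDRRVPGVMVFIGDETMKV
>portal_fam2
GQLKELIEKLASKVWATHEREDLGVLRGFDWHLNFMSIDNEPTTAEVLPKVKIGELVKPIVAAIVDWQTT
NYDPKFKWFVGEVLDRIPIVLFVPITSPYVNYKMMAKVVERGAFGGRLFQRTQVNRDQDDLLLICDPLEI
DNLGWASKMFARLLLHKRLKWCPIMFTFESATNRLLSPNDLNRTDVEERDVTVTSNKAQTDQLITTLFVQ
LGGTPNTLIGGRNNSNDLNIPRRGRAIVSPKDKIHTLEDASNHMDEGDIDMISQILALSDVGAIVPDTIK
NLLANSFVADPRKCQKRQADRKAELFGYCAYAPPKESISVIQDTPSSTSYGNSERAKASTLQRFRAHNYL
VVALTYKWRACLMSCDADYPMIYYPAGTIPPFWPRNCGLVPIKEDYVGQLETRFSGIQNQNVVRLRYVYE
NCQEVLITGSPPNSLVDDTQQALLVLFYNTERQDLVMRDSGLVLSLEPRGIGLEYTGGGERIRLLGPTDY
PINSPIYIAPAIASFGEPCGRVEAIQNYAVGDGITSAVMGLTIRRVFLDMVFISDEDAKV
>portal_fam3
GQLFELIPKLALKVWATHHREEGIVCDIFDWHYNIMSIDNMPEVDLVPNKVDIGELVLPLKAGTHEWCTT
NEDPGFKWVVFEVLDRNPFPQQVPIYSPYVNYQMEKKSQERIFFGGRLDGRTQPNRDQDDCILICDEHEK
DLLGWASPMFARLLLHQRLDWQPGMFTFEGPGNRLLSILALNDTDREELVVTVCSNRDQTDQDITTEFCD
LGGTPNTLIGGRNGSWALNIGRRGRSIVGVIDVQHTGEDSSHRMDECDIDPISLIEALSDVGAYVYDLQK
NLLTRVFAAFNRGCQKRQADGKARLIGVCAYAPPKLSISKLLDTPPSTSYGMSIEVKIVQAQRFRARNSL
VVALTYKWRACKMSSPDDYPVIYYPALTIPDFWPTNYGKVPIKLDYVGQLITRFSAIQNQNVQRLMYAYL
NCQSVLIWGLPPNIGPDDTQQALLVTFYYTERQEERMENSGGVPSLEPRARGLEYTGLGERIRLLEPADY
LINSPIYIAPAAASFGEPVGRVFQIQNYTKLDGITSARLGLTIRRVPGVSVFIGDEVMKV
>portal_fam4
GQLKESIEKLALKAWATHEREEAGVLDFFRWHPKIMSIDKMPETALVLNVVDIAELVKPLVAGISLWQTT
TYDTKLKTVVFEVLDRRPFPLGVPIYSMTVAYQMEFKVVYRIFDGEPLDQRVQPERDQDDSLDICEPLEK
DLLGFASPMTGRLLLTSRATWCPIMFEFESPTRRTLSPNDLTGTDKEEMIVTVTSNKAQTDLDITTLFVR
LGGQPNTLIGGRYTSFALFIPPRGRAIVGVIDIIHPLIDSSHHMDEGDIQPISLILALSHVGAIVYDTIK
RLLADSFGGDMRGDFKRQADPKDRLIEYLAYAPPKNSISSILDTPPWTLYGRSEEVKRNEAERFVAHNGL
VLALTYKWRAAVMSCDADYPGIYYPAVRIPLVWPTNYLLVPILTDYVGKLITRFSVAQKQNVVRLRYVIE
NCRSILIVGLPPNSLVDDTQQELLVTFYYPERPVEKMENSGGVLILEPRGFGLEYTSENERIRLLGPTDD
PVNSPIYIAPAIASFGEPVLRVFAIQNYKKLDGITSAVMQLTDRRVPLVSVLIFDEVMKV
>portal_fam5
GQLLELIEKLLLKVWAHVERIEAGLLDIFEWHLNIMSIDNPPETSLVLNAVDIGELVKPLVAGIVEWQTT
NYDPGFKSVVGEVLDPIPFPSFVPIYLPYVNYCMEKKNDYRIFFGGRLDQHTQRNRDQDDSNLITAALEE
DLLGWASPMFARLLLHSVLDWCPIMFWGEDPTNRSLSPNHLNGTDNEEMVVTVTSTYAQTDQDITTLFKR
LGTTPGTLIFGTNNPNALNIPRRGRANVGVIDIIITPFDSSHHMDLYDIRPISLILALSDVTAIVYDTSK
NLMANSFLADNRGCQYRQADDKAALINYCSNAPPKELTSFILDTPPSVSYGHSEEVKRNTAQRFRAHNGL
VVALTNKWRACVMPRDADYPVIYGPAGTIPPFWPTNYGLVPILTAFVGQLETRFSGIQNQNVVRLAYVAE
GCQSVLIVGTPPNSLTDDTLQAILVTFYYTERVEEKMENSGGVLSLEPAGIGLEYTTLGERIRLLGPTDL
PINSPIAIAPAIISFGEPVGLVFAIQNPVKLIGITSAVMGLIIRTVPGVMVLIDDTVPKV
>portal_fam6
GQLVELIEKLALKVWAGTEREEAGVLDIFDWMLNIMSIDYMPQTALVLLPVDIGELVKPKVAGIVEWQLT
NYDPKSKWVLFETLGRIPFPLFVPIYSPYVNYQDEKKIVYRILFGGRLDQKTQLNRDQDDLLLICDKLEK
DLLGWAHPMAAPLLLHSRLDTCWIMPTFESPTNRLLSPDDTNGTDPEEMVVTVTLNKAFTGQPITTLFTE
PGGTPNTLIGGRNNSEALNIPRRMIAIVGVIDIITTLEDDSWHMDSYDIVPIQLILASSDVYAIVYDLIK
NLLANSFVADNRGCQKRQADRKARLTGYCAYAPPKESISFIIDTPPSTPYTSSLEDKRATAQRFRAMNAL
VSYLNYKGKDCVMSGVLDYQVIYYPAGTIPPFWPTNYGLLMISWDYVAQLITRFSFAANPNVVRLRYEYQ
NCQMVLIVGLPPNSLVDDTQQALLVTPPYTERQECKMENSGGVTSHEPRSIPLEYTGLGERIRLLGPTVY
LITSPIYIAPAIESFRQPVGRDGALQNYAKLDGIRSAVMELTIRRFPGVPVFSADRVMKS
>portal_var1
IQVKELIEKLASKFWATHEREEEHVLDLFDKHLNIWSIQNLPETALVLLQVDVGELVKPRCAGRVEWHTT
NYDAKFLWVVFVSLDRKPFPDEVPIYSVYSNRQMTLKVVYRSFFGGRLDLRTQPNSDQDDSLLICIKLLK
DLLGWLSPRFEELLLHQRFDWCPIMVTFESPTNGLLSGQDLNGTDNEEMVVSVTSNKEPTDQCIITLTVR
LGGTPNTLIGGENNSNALNFPRGGVAIVGVIDIDHTLEDQSHHMDEYDIDLISLENDLLDSGAIVWDTVK
NLLANSKVAKARGAQKRQADKKAPLIAGCATQCPKNSKSYILDTPPSTSYSWSEEVWRNTSARFRAHNGL
VVALTYKWRACVFTCDADVPVIYYPISTLPPFWPTNYGLFPLRTLYVGQDGTRFSGIQNLNVKGLQYTYE
NCQIVWIVFNPGNSRYDDGQQTFLLTDYYTERSVEKMANADGRLSLESRGIGLEYTGLGITICLLGGTDY
PINAPIYIAPAIASFGEPPGRVFADQRYAKLKTSQSAPGGHTDRRVPGVMVFIGDETMKV
>portal_var2
GQLKELIEKLASKVWATHEREDLGVLRGFDWHPNFMSIDNEPTTPEVLPVVKIGELVKPIVAAIVDWQTT
NYDPKFKWFVGEVLDRIPIVLFVPITSPYVNYKMMAHVVERGAFGGRLFQLTQVNRDQDDLLLHCDTLEI
DNLGAASKMFARLLLHKNLKWCPIMFTFESATNRLLSPNDLNRTDVEERDVTVTSNKAQTDQLITTLKVQ
LGGTPNTLIGGRNNSNDLNIPLRGRAIVSPKDKIHTLEDRSLHMDEGDIDMISQIAALSDVGAIVPDTIK
NLLANSFVADLRKCQKRQADRKAELFGDCAYAMPKESISVIQDLPSSTSYGPSERAKASTLQRFRAHNYL
VNALTEKWRACLMSCDADYPMIYYPIGTIPPFAPRNCGLVPIKEDYVGQLETRFSGIQNQNVVRLRYVYL
NCQEVLITGSPPNSLVDDTQQALLVLQYNTERQDLVMRDSGLVLSSEPRGFGLEYTGGGERIRLLGPTDY
PINSPIYIASAIASFGEPCGRVEAIQNYAVGDGITSAVMGLTIRRVFLDMVFISDEDAKV
>portal_var3
GQLVELIPKLALKAWATHHREEGIVCDIFDVHYNIMSLDNMPEVDLVPNKVDIGELVLPLKAETHEWCTT
NEDRGFKWAVFEVLDRNPFPQQDPIYSPYVNYQMEKKSQERIFFGGRLDGRTPPNRDQDDCILICDEHEK
DLLGWASPMFARLLLHQRLDWQPGMFTFEGPGNRSLSILALNDTDREELVVTVCSNRDQTDQDITTEFCD
LGGTPKTLIGGRNGSWASNIGRRGRSIVVVIDWQHTGELSSHRMDRCDIDPISLIEALSDVGAYVYDFQK
NLLTRVVAAFNRGCQKRQADGKARLIGTCAYAPPKLSLSKGLDTPPSTSAGMSIEVKIVKAQRFRARNSL
VVAQTYKWRACKMSSPDDYPVIYYPALTIMDNWPTVYGKVPIKLDYVGQLITRFSAIQNQNVQRLMQAYL
NCQSVVISGLPPNIGPDDTQQALLVTFNYTERQEERMENSEGVPSLEPRARGLEFTGVGERIRLLEPADY
LINSPIYIATAAASFGEPVGRVFQIQNYTKLDGITSARLGLTIRRVPGVSSFIGDTVMKV
>portal_var4
LQLKESIEKLALKAWATHEREEAGVLDFFRWHPKIMSIDKMPEEALVLNVVIIAELVKPLVAGISLWGTT
TYDTKLKTVVFEVLDRRPFPLGVPIYSMTVAYQMEFKVVYRIFDGEPLDQRVQPERDQDDSLDICEPLEK
DLLGSASTMTGRLLLTSRATWCPIMFEFISPTRRTLSPNDLTGTDKEEMIVTVTSNKAQTDLDITTLFVR
LGGQKNTLIGGRYTSFALFIPPRGLAIVGVIDIIHPLIDSSHHMDEGDIQPISLILYLKHVGAIVYDTIK
RLLACSKGGDMRGDFKRQADPKDRLIEYLAYAPPKNSISSILDLPPWTLYGRSEEGKRNEAEGFVAHNGL
VLALTYKWRAAVMSCDADYPGIYYPAVRIPLVWPTNYLLVPILTDYVGKLITRFSVAQKQNVVRLRYVIE
NCRSTLIVGLPPNSPVDDRQQALLVTFWYPERPVEKMENSGGVLILEPRGFGLEYTSENERSRLLGPTDD
PVNSPIYIAPAIASFGEPVLRVFAIQNYKKLDGCTSAVMQLTDRRVPLVTVPIFDEVMKV
>portal_var5
KQLLELIEKLLLKVWAHVERIEAGLLDIFEWHLNIMSIDNPPETSLVLNAVDIGELVKPLVAGIVEWQTT
NYDPGFKSVVGEVLDPIPFPSFVPIYLPYVNYCREKKNDYRIFFGGRLDQHTQQNRDQDDSNLITAALEE
DALGWASPMFARLLLHSVLDWCPIMFWGWDPTNRSLSPNHLNGTDNEEMVVTVTSTYAQTDQDITTLFKR
LGTTPGTLSFGTNNPNALCIPGRGRANVGVIDIIITPFDSSHHMDLYDIRPISLILALSDVTAIVYDTSK
NFMANSFLADNRGCQYRQASDKAALINECSNAPPAELTSFILDTPPSVSYTHSEEVKRNTAQRFRAHNGL
VVAGTNKWRACVQPRDADYPVIYGPAGYIPPFWPTNYGLVPILTAFVGQLETIFSGIQNQNVVRLAYVAE
GCQSVLIVGTPKNLLTDDELQAILDTFYYTERVEEKMENSGGVLSLEPAGIGLEYRTLGERIRLLGPTDL
PINSPIAIAPAIINFGEPVGLVFAIQNPVKLIGITSAVMGLIIRTVPGVMVLIDDTVPKV
>portal_var6
LQLVELIEKLALKVWAGTEREEAGVKDIFDWMLNIVSIDYMPQTALVLLPVVIGELVKPKVAGIVEWQLT
NYDPKSKWVIFETLGRIPFPLFVPIYSPYVKYQDVHKHVYRITFGGRLDQKTQLNRDQDDLLLICDKLEK
DLLGWAHPMAAPLLLHSRLDTCWIMPTFESPTNRLLSPDDVNGTDPEDEVVTVTLNKAFTGQPITTLFTE
PEGTPNTLIGGRKNSEALNIPRRMIAIVGTIDIITTLEDESLHMDSYDIVPIQLILASKDVYTIVYDLIK
NLLANSFVADNRGTQKRQADRKARLTGYCAYAPPKESISFWIDTPPSTPYTSSLEDKRATAQYFRAMNAL
VSYLDYPGKDCVMSGVLDYQVIYYPASTITPFWPTNYGLRMISWDYVAQLITRFSFAANPNVVRLRYEYQ
NCQMVLIVGLPPNSLVDDTAQALLVTPPYTERQECKMENSGGVTSHEPRSIPLEYTGLSERIRLLGPTVY
LITSPIYIAPAIEIFRQPVGRDGALQNYAKLDGIRSAVMELTIRRFPGVPVFSADRVTKS
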