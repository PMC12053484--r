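>MCP_fam1
LAVMGAKDLARTEQLCLYKQLLPRKEGYLYQTPQVTNCAAALTLFEVLGQEVAESNLESVYLTFDKALYQ
RRAVTAFIGAKCFQPAQVTSKLSRFEVGPYELKGEMCEKARNSTESIYNISRADTKWNTGADESQTLEGE
GQECENKNLDLHCDQMYGVVLTDLGDNYGELASISVTIGLMLDDEKKNSLFIGNQEQAEMEPTSFHARFY
DGACTTNNSAVLAIILFKTDTEDDEAAIGNENDLKRQSCRCEYTYPRNSGVGAGRDADRKTKFKVSAYYV
KQLIRSDSDSRAITKKVPCYMYPTAEPKLPIKMCKLPSQAAQEGSCNTEFLSGAADSLLLKRVSILGKIG
KFKTGGYLSRALIKFQLEEQIQIRNSTDGRYLEYGREQQAEVQKLLDIHSAAASSIALPTMRNGVLELAL
RCSVLRRVKQYVRKVQLCLCQASNQLRAKD
>MCP_fam2
TVVIGADGLAFTPQTCERKISLRKKGGYPYQLPSVTPCAAFLTLSTDLVQEVALFNRESNILTRLHALNL
ELKVHARIGAACFQPDYVTSVLTRPENRSYELKGELCYKEGNSVEIIYNIKRARRGGNTGLTESQTFESE
DQECENKNLDLHHDRVGGVVRTDGGRDIGEVRSISSTIGLRLDDEKGIILFIALQEPADVEPTSFTLPFG
LNACEGNNSACLALILFKTDVEWDEAIIGQENDPKEQSCDFEYTYPRIQGTGTAIKDDRVTRNKISDYIS
KDHIRSESDSRGITKKVKDYMLPTAIPFLKIKMCKLPSGALQEASCNTEFLSGTADILLSLRLSILGTGV
KVDTGGYGSRALIKANLDEDILIRDVTDGRYLEQGRELELEKQKLANNISAALSSPANATACLGVLELAT
RCSVLRIVKQQGRKLQLCLCLASSQLRGKV
>MCP_fam3
LNVMGAKGKAFTITLCEYKISLARKEGYPLQLPGVTNCAAGLTLFEVLVQECALENRGSNGLHRLLALYS
RRKVHAFAGAKSFQLAYVMTILTRFENGALELKGEGCYKEGNSTESIYNISRAITGGNTNATESTTLEGE
DIECENKPLDLHCDGVYGEVRSEGGDRGQEPRSISVTIGLMLDDEKGAIKFITNQEPADMEPTSFHARFG
RGACPTNNSATLAIILFKTDTEDDEALIGNENDPFAGSCRFEETYPRIRGTGAARKLDRVTRFKISVYYV
KDHIRSQSDSREITKAVKDYMLETAIPGLRMKMCKLPSAAAQEESCNTVFLSGTAISLLSLRLHILGKRV
KVDTGGYLPRALIKFNLEEQIQIRQVTDGRYLELGRNLQLEKQKLLNNKQRAASSPDLPTMCNGVRFLAT
YCGTVRRVIQYTRHLQWCLCLASIHLRAKD
>MCP_fam4
LNVGGAKALAQTEQLFEWKISLRRKEGYCYQLPQVTRCAAELTLFIVLVQCVTLSNRESNGLTRLVALLL
ERKVHTFIGAKCFQPAYVTSILTSFENGSYELKAELCYKEGNSCESIASISRAITGGNTGATESNTLEGE
DQECENKNEDLHCDDVGDVVRTDGGTEGGELLSITSTIGLMLDDEKGIILFIQNSEPYDMEPMSFHERFG
LGRCVTNNAACLNIILFKTGKVDTEVLIGKDNDPFRQFCRFEYTPPRGRITGAAEKADRVLRFKISVYYV
KDHIRSDSDSREITKKVNDYMYPTAIPKLDIKMCKLPSGTAQEASCNTEFLRLTADSTLPLRLAILGKIN
KVDTGRYLSLALIKFNLEEQIQRRNVIDGVALEQGREMVLEKQKLLNNKSAGASSPALPTMCQGVLELPT
RCSVLRRVKQYVRKLQSCECLNSIQLRAKD
>MCP_fam5
LSVSGCRGLAFTILYCAYKISLARKELYQYKLPQVTNMAAAESLFEVSLFEVALSTRTYNKLTRLRAKYL
MRKVHAFIDAKCFGPAYVTSILPRFENGAYTLKGELGYEEGNSTPSIDNISRAITGGNTGATESQTLEGE
DLACEDDNLDLHCDQVYGVVRTDGIDRGGRGDRISVTIGLMLDDELGIILFIANLEPADMEPTYFHRRFG
LISCETENSACLAIVLFKTEREDDEQLIGNENDPFHQSCRVEYTYVRAYGRGSARTIDRVTRFKISGYYV
KDHIRSTSDSRVITKAVKDNMYPGAIPMFPGKMCKLKSGAEQEASCNTEFLLGTADSLLSLRLSDLGILV
IVDTSGYLSGHLIFFNLEEQIQIRNVTDGRYLPQGEQYQLTEQFLLNNKTAAASSPAVPTMCQGVLELAT
RFSVLSRVKQKNRKLQLCLALASIQLRAKD
>MCP_fam6
LNVVGAMGLAFGITLSEYKISLARLEGYHYQLVQVANCGAALTLFEVLIQEVALSNRFSSGPTRLKALYL
RRKFHAFHGAKCFQPAYVTSILTRLEPGSYEVKGELCAKLGNSTHSIYNISRAITYGNTGATEVQTLEGE
DQNCENKNLSLLCDQVYGVVKTDGGDRNGLLRSISVNIGLMLADEKQIILFIANLEPADMEMTKFLLRFG
LGANETNGSACVAIILFKTDTEDDEALSGNENDPVRQSCRLSLTYPGIRGTGAARKADRVTRFKISVIYV
KGHIREDSDSRKNRKKVKDVMYPTAIPKLPILMCKLGSGAADEARCNTEFLSGTADSLLSLRLSFLGKIG
KSDRGGYLSAALIKFNREEQIQIRYVTDGLTLEQGLELQLEKQKLLNNKSAAADSSALPTMCNGSLELAT
RCSVLRRTKQYVRKLQLCLGLASIQLRYKD
>MCP_var1
LGVMGAKDLPRTEQLCLYKQLLPRKEGYLGQTPQVTNCAAALSLFEVLGQESAESNLESVYLTFDKALYQ
RRAVTAFIGAKCFQPAQVNKKLSRFEVGPYELKGEMCEKAFNSTESIYNISRADTKWNTGADESQTLEFE
GQECENKNLDGHCDQMYGVVLFDLGDNYGELASDSVTIGLMLDDEKKNSLFIGNQEQAEMEPTSFHARFY
DGACTTNNSAVLAIILFITDTEDDEAAIGNENDLKRQSYRCEYTYPRNSGVGAGHDADRKTKFKISAYYV
KQLIRSDSDSHAITKKVPCYMYPTAEPKLPIKMCKLPSQRAQEGSCNTEFLSGAADSLLLKTVSILGKIG
KWKTGGYLSRALIKFQLEEQIQIRNSNDGRYLEYGREQQAEVQKLLDIHSAAASSIALPTMPNGRLELAL
RCSVLRRVKQYVRKVQLCLCQASNQGRAKD
>MCP_var2
TVFIGADGLAFTPQTCEHAISLRKKGGYPYQLPSVEPCSAFLTLGTDLVQEVALFNRESNILTRLHALNL
ELKVHARIGAFCFQPDYLTSVDTRPENRSYELKGELCYKEGCSVEIIYNIKQARRGGNTGLTESQTFESE
DQEQENKNLDLHHDRVGGVVRTDGGRDIGEVRSISSTIGLRLDDEKGIILFIALQEPADVEPTSKTLPFG
LNACEGNNSACLALILFKTLVEWDLAIIGQEYDPKEQSCDFEYTYPRIQGTGTTSKDRRVTRNKFSDYNS
KDHIKSESDSRGITKKVKDYMLPTAIPFLKIKMCKLPSGALQEASCNTEELSGTADILLSLRLSILGTGR
KVDTGGYGSRALIKANLDEDILIRDVTAGRYLEQGRELELEKQKLANNILAALSSPANATACLNVLELAT
RCSVLRIVKQQGRKLQLCLCLASSQLRIKV
>MCP_var3
LNVMTAKGKAFTITLCEYKISLALKEQYPLQLPGVTNCAAGLTLFEVLFQECDLENRGSNGLHRLLALYE
RRKVHAFAGAKSFQLGYVITILTRFENGALELKGEGCYKEGNSTESIYNISRAITTGNTNATESTTLEGE
DIECENKPLDLHCDGVYGEVRSEGGDRGQEPRSISVTIGLMLDDEKGAIKFITNQEPADMEPTSFHAEFG
RGACPTNNSATLAIILFKTDTEDDEALIGNENDPFAASCRFEELYPRIRGTGAARKLDRVTRFKISVYYV
KDHIRSQSDSDEITKAVKDYMLETAIPGLRMKMCKLPSAACQEESCNGVFLSGTAISLLSLRLHILGKRV
KVDTGGYLPRALIKFNLEEQIQIRQVTDGRYLELGRNLQLEEQKLLNNKQRAASSPDLPTMCNGVRFIAT
YSGTVRVVIQYARHLQWCQCLASIHLRAKD
>MCP_var4
LAVGDAKALAQTEQLFEWAISLRRKEGYCYQLPQVTRCAAELTLFIVLVQCPTLSNRESNGLTRLVALLL
ERKVHTFIGAKCFQPAYVTVILTSFENGSYELKAELCYKEGNSCESIVSISTAITGGNTGATESNTLEGE
DQECENKNEDLHRDDVGDVVRTDGGTEGGELLSITSTIGLMLDDEKGIILFAQNSEPYWMEPMSFHERFG
LGRCSTNNAACLNINLFKTGKSGTEVLIGKDNDPFRQFCRFEYTPPRGRITGAAEKADRVLRFKILVYYV
KDHIRSDSDSREPTKKVNDYMYPTAIPKLDIKMCKLPSGTAQEASCNTEFLRLTADSTLPLRLAILGKIN
KVDTGRYLSLADIKFNTEEQIQRRNVIDGVALEQTRPMVLEKQKLLNNKSAGASSPASPTMCQGVLELPT
RCSVLRRVKQYVRSLQSCECLNSIQLRAKD
>MCP_var5
LSVSGCRGLAFTILYCAYKISLARKELYQYKLPQVLNMAAAESLFSLSLFEVALSTRTYRKLIRLRAKYL
MKTVHAFIDAKCFGPAYVSSILPRFENGAYSLKGELGYEEGNSTPSIDNISRAITGGNTGATESQTLEGE
DLAREDDYLDLHCDQVNGVVRTDGIDRGGRGDRISVAIGLMLDLEKGIILFIANLEPADMEPTYFHRRFG
LISCETENSACLPIVLFKTFREDDEQLIGNENDPFHQSCRVEYTYVRAYGRGSARTIDRVTRFKISGYYV
KDHIRSTSDSRVITKAVKDNMYPGAIPMRPGKACKLKSGALQEASCNTEFLLGTPDSLLSLRLSDLGILV
IVNTSGYLSGHLIFFNLEEQIQIRNVTDGRYLPQIEQYQLTEQFLLNNKTAAASSQAVPTMCQGVLELAT
RFSVLSRVKQKNRKLQLCRALASIQLRAKD
>MCP_var6
LNVVGAMGLAFGITLSEYKIPLARLEGYHYQLVQVVNCGAALTLFEVLIQEVALSNRFSSGPTREKALYL
RRKFHAFHGAKCLQPAVVTSILTRLEPGSYEVKGELCAKLGNSTHSIYNISRAITYLNTGATEVQTLEGE
DQNCENKNLSLLCDQVGGVVKTDGMDRNGLFRSLSVNIGLMLADEKQIILFIANLEPADMEMTKFLLRFG
LGANEANGSACVAIILFKTDTEDDEALSGNENDPVRQSCRLSLTYPGIRGTGAARKADRVTRFKISVIYV
KGHIREDSDSRKNRKKVKDVMYPTAIQKLPILMCKLGSGAADEARCNTEFLSGTAISLLSLRESGLPKIS
KSDRGIYLGAALIKFNREEQIQIRYVTFGLTLEQGLERQQEKQKLLNNKSAAADSSALPTMCNGSLELAT
RCSVLRRTKQYVRKLQLCLGLASIQLRYKD
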