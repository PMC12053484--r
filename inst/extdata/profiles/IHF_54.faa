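>IHF_54_fam1
TADGLRGKNSFELAITEIINPLLGPRYRRQKSPPTKKCSHKHSPSTQSQIGNQIEIIDDKSGLAFDLLTV
LTGRVSDNEVPIIFADTEKTLIKRETTRTNCLNRYVHEMAVQSKGEYDIQDLQTGDLHVV
>IHF_54_fam2
TADGLRGKNSFELAIPEIINPRLYPRKRSSKSTIKFPCVYKHSPSKQSQIGNQIEHIDDKGGHQFDLGTV
LTGRNSDNEVPYIWGDTAKTTIKINSGRTNCLNQAFHEMAVQGKQEYDISDLQTPGLEVV
>IHF_54_fam3
TADGLRAGISFEGAIPEIINPRLIPRYRSSKYDKKFPGVYKHGPSEQSQIGNQGEDLDDKTGLQFDLGVV
LTGRVSDNELPIIFADTAKTTLNTESTTTNCLLQAIHEMAVQSPREYTISDLQTGGLESV
>IHF_54_fam4
TADGLRMKNTLELAIPEIINPRLIPRYRSSVSPPKFPCVESGSPSEQSQTGHGHSGIDDKSGLTFDLGDV
TTGRVSDAEVPIYFEDTAETTNKIESTRTNCLNQAIAEMAVKFKGEIDISDLMTGGDLVV
>IHF_54_fam5
TVDGLRGKNSFELDIPEIINPLLIPRYRSSKSPPKFPCVYKHDPSEQSQPDNQIEIIDDKSKQQFDLGTV
LDGRVSDNHVPIIFADTAKTTIKIESTRTNLGTQAVHEMAKQSKGEYDIKDLQTIGLEVV
>IHF_54_fam6
TADGLRGKNSFELAIKEIINPRLIPRYKSSKSPPKFPCKVKHSPSRQSDIGNLIELIDDKSGLQFDLGTV
LTGRVSDNEVPIVFADTAKTTIKIFSTPTNWLNQGVHSMAVQSVGEYDASDVCYGGLEVV
>IHF_54_var1
TADGLRGKNSFELAITEIIDPLLGPRYRRQKSPPTKKCSHKHSPSTQSQIGNQIEIIDDKSGLAFDLLTV
LTGRVSDNEVPIIFADTEKTLIKRETTRTNCLNRYVHEMAVQSKGEYDIQDLQTGILHVV
>IHF_54_var2
TADGLRGKNSFELAIREIFNPRLYPRKRSSKSTIKFPCVYKHSPSKQSQIGNQIEHIDDKGGHQFDLGTV
LTGRNIDNEVPYIWGDTAKTTIKINSGRTNCLNQAFKEMAVQGKQYYDISKLQTPGLEVV
>IHF_54_var3
TADGLRAGISFEGAIPPIINPRLIPRYRSLKYDKKFPGVYKHGPSEQSQIGNQGEDLDDATGLQFDLGVV
ITGRVSLNELPIYMADTAKTTLNTESTTTNCLLQAIHEMAVQSPREYEISDLQTGGLESV
>IHF_54_var4
TADGLRMKNTLELAIPEIINPRLIPVYRSSVSPPQFPCVESGSPSEQSQTGHGHSDSDDKSGLTFDLGDV
TTGRVSDAEVPIKFEDTAETTNKIESTRTNCLNQAIAEMAVKFKGEKDISDLMTGGDLVV
>IHF_54_var5
TVDGLRGKNSFELDIPEIINPLLIPRYRSSKSPPKFPCVYKHDPSEQSQPDNQIEIIDDKSKQSFDLFTV
LDERVSDNHVPIIFADTAKTTAKIESTRTNIGTSAVHEMAKQSKGEYDIKDLQTIGLEVV
>IHF_54_var6
TADLLRGKNSFELAIKEIINPRLIHRYKSSKKPEKFPCKVKHSPSRQSDIGNLIELIDDKSGLSMDLGTV
LTGRVSDNEVPIVFADTAKTTIKIFSTPTNWLNQGVHSMAVQSVGEYDASDVCYGGLEYV
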