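>synthetic_mesophilic_form2_baseline synthetic Rubisco-like composition fixture
CKATVLIVSAIQLDRKMEKETLSVLETFPAWVLGPFAEALLSDVEDQPFSQIYWPNVNRV
HPEAMDDSWRLAHVKAAVADGVVAAIGPLNYPLWAVLIHHGWNTMCHKPGVMADVIRIRL
RVLGLALLLNGRKAFTNIHVGFGGLIPTNLGGTTVAKQSDANPIVAERLTLPTLAVGDQG
ECDSFEGPNKHACFNKLCAKDRSVPTIQLNRELKDLDYVTVLWGAAGNRRFEQCGGFHGE
GVCTADQTHQAPSLYLDEDPAIYPTFRKSIPVNSNILYSARGGTRDGLLAALANRGTKSF
LLTLYALMTINQTDNPMGAKAEMFAMSAVQHFSDLNKPDGRQSSYAQVQPIHGAVPEGEI
KRQDGVMAKLPATGAAEKWVSNRGSSAPLFGKIRVQGHKLDGDVAVSSEIVVLPIERILM
FAIPGAQLDASDFDQKKIGFVVLLIDSANKNGDPTEKTEY
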