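sample,img0001,img0002,img0003,img0004,img0005,img0006,class
imgS0001,1.3709584471466685,0.45545012324121936,-0.36723464274097534,1.392116375934271,-1.4936250673162905,-0.040698475151214927,0
imgS0002,-0.56469817139608869,0.70483733722881914,0.18523056486560932,-0.47617392305467421,-1.4704357414367966,-1.5515448223475896,0
imgS0003,0.3631284113373392,1.0351035219699223,0.58182372736550669,0.65034856072630509,0.1247023861970068,1.1671695492356817,0
imgS0004,0.63286260496104041,-0.60892637540721106,1.3997368272926782,1.3911104563900005,-0.99663913488403733,-0.27364570137408067,0
imgS0005,0.40426832314099903,0.50495512329797032,-0.72729205947446507,-1.1107888794478988,-0.0018226143047081959,-0.46784532467225354,0
imgS0006,-0.10612451609148403,-1.7170086790733425,1.3025426320441438,-0.8607925868778421,-0.42825888142581525,-1.2382523279862143,0
imgS0007,1.5115219974389389,-0.784459008379496,0.33584811975207446,-1.1317386808537699,-0.61367160644949537,-0.0077620337773266299,0
imgS0008,-0.094659038413097557,-0.85090759417651829,1.0385060986976211,-1.4592139995023958,-2.0246778454191077,-0.80028217795165957,0
imgS0009,2.0184237138770418,-2.4142076499466318,0.92072856829064631,0.079982553241161172,-1.2247479503599861,-0.53349232995043649,0
imgS0010,-0.062714099052420993,0.036122606892255632,0.72087816286686246,0.65320433964919,0.17951644111793794,1.2876752455845886,0
imgS0011,1.3048696542234852,0.20599860020025385,-1.043118938567855,1.2009653755984941,0.5676205944235353,-0.1755258702421274,0
imgS0012,2.2866453927011068,-0.36105729854866631,-0.090186386610706687,1.0447510871677252,-0.49287735355347473,-1.0717823841506759,0
imgS0013,-1.3888607011123393,0.75816323569951694,0.62351816199954357,-1.003208646839848,6.2884065351124079e-05,0.16320688246738232,0
imgS0014,-0.27878876681737136,-0.72670482707657524,-0.95352335777234398,1.8484819016727465,1.1228896433799662,-0.36273841562794984,0
imgS0015,-0.13332133639365804,-1.3682810444192945,-0.54282881457385668,-0.66677340875781721,1.43985574297619,0.59001354798733874,0
imgS0016,0.63595039807007436,0.43281802588871715,0.58099649768168249,0.10551381245606943,-1.0971137684058216,1.43242192773099,0
imgS0017,-0.28425292141607239,-0.81139317618667162,0.76817873783459101,-0.42225588186885599,-0.11731956025017684,-0.99269251110949275,0
imgS0018,-2.6564554209047757,1.4441012617212527,0.4637675885401672,-0.12235017195497132,1.2014984009197012,0.45465029758028258,0
imgS0019,-2.4404669285755194,-0.43144620261334543,-0.88577629740967945,0.18819303450149788,-0.46972958056630093,0.084898058678487293,0
imgS0020,1.3201133457301921,0.65564788340220681,-1.0997808986478557,0.11916095799700638,-0.052469484938996329,0.89556558226454475,0
imgS0021,-0.30663859407847455,0.32192526520394654,1.5127070098049282,-0.025092550867402877,-0.086107298237089555,-0.22977813894626645,0
imgS0022,-1.78130843398,-0.78383894088037542,0.25792143753203084,0.10807272794203257,-0.88767901790643156,0.8366190684606134,0
imgS0023,-0.17191735575962136,1.5757275197919773,0.088440229159586353,-0.4854352358466677,-0.44468400488473814,-1.7450558613366933,0
imgS0024,1.2146746991725987,0.64289930571731635,-0.12089653753908947,-0.50421713068790353,-0.029444879088238146,1.6894589213133737,0
imgS0025,4.8951934612649648,3.0897606465996055,-1.1943288951605282,-1.661099079914812,-0.41386884905792354,0.86477797851857796,1
imgS0026,2.5695308683938003,3.2765507472914628,0.61199689804038693,-0.38233372687381795,1.1133860233682031,-0.15077598888574781,1
imgS0027,2.7427306172310706,3.679288816055271,-0.21713984574652084,-0.51265025787780039,-0.48099284165398187,-1.4490071301391676,1
imgS0028,1.2368369148052198,3.0898328865790816,-0.18275670633192173,2.7018910003447982,-0.43316903260072903,0.64300870004198163,1
imgS0029,3.4600973548312712,0.0069099168470652117,0.93334632857116007,-1.3621162311897186,0.69686257655210282,0.48319386381476764,1
imgS0030,2.3600051240398807,3.2848829535306594,0.82177311050824919,0.13725621855860692,-1.0563684131709081,-0.0063556264213887126,1
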