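subset,algorithm_id,dsl,label,tp,tn,fn,fp,post_prev,sens,sens_lo,sens_hi,spec,spec_lo,spec_hi,ppv,ppv_lo,ppv_hi,npv,npv_lo,npv_hi
adults,h1,1H,1 H ever,15,7429,54,2,0.2,22,12,32,100,100,100,88,73,100,99,99,100
adults,h1_er1,1H | 1ER,1 H ever OR 1 ER ever,16,7427,53,4,0.3,23,13,33,100,100,100,80,63,98,99,99,100
adults,p1,1P,1 P ever,62,7188,7,243,4.1,90,83,97,97,96,97,20,16,25,100,100,100
adults,p1_spec,1P(spec>=1),1 P ever by a specialist,56,7377,13,54,1.5,81,72,90,99,99,100,51,42,60,100,100,100
adults,p2_1y,2P/1y,2 P by any physician in 1 YR,58,7363,11,68,1.7,84,75,93,99,99,99,46,37,55,100,100,100
adults,p2_2y,2P/2y,2 P by any physician in 2 YR,58,7359,11,72,1.7,84,75,93,99,99,99,45,36,53,100,100,100
adults,p2_3y,2P/3y,2 P by any physician in 3 YR,58,7352,11,79,1.8,84,75,93,99,99,99,42,34,51,100,100,100
adults,p3_1y,3P/1y,3 P by any physician in 1 YR,55,7398,14,33,1.2,80,70,89,100,99,100,63,52,73,100,100,100
adults,p3_2y,3P/2y,3 P by any physician in 2 YR,55,7395,14,54,1.2,80,70,89,100,99,100,60,50,71,100,100,100
adults,p3_3y,3P/3y,3 P by any physician in 3 YR,55,7393,14,38,1.2,80,70,89,100,99,100,59,49,69,100,100,100
adults,p2_spec_1y,2P(spec>=1)/1y,2 P with >= 1 P by a specialist in 1 YR,54,7404,15,27,1.1,78,69,88,100,100,100,67,56,77,100,100,100
adults,p2_spec_2y,2P(spec>=1)/2y,2 P with >= 1 P by a specialist in 2 YR,54,7404,15,27,1.1,78,69,88,100,100,100,67,56,77,100,100,100
adults,p2_spec_3y,2P(spec>=1)/3y,2 P with >= 1 P by a specialist in 3 YR,54,7401,15,30,1.1,78,69,88,100,100,100,64,54,75,100,100,100
adults,p3_spec_1y,3P(spec>=1)/1y,3 P with >= 1 P by a specialist in 1 YR,53,7419,16,12,0.9,77,67,87,100,100,100,82,72,91,100,100,100
adults,p3_spec_2y,3P(spec>=1)/2y,3 P with >= 1 P by a specialist in 2 YR,53,7418,16,13,0.9,77,67,87,100,100,100,80,71,90,100,100,100
adults,p3_spec_3y,3P(spec>=1)/3y,3 P with >= 1 P by a specialist in 3 YR,53,7418,16,13,0.9,77,67,87,100,100,100,80,71,90,100,100,100
adults,h1_p2_spec_1y,1H | 2P(spec>=1)/1y,(1 H ever) OR (2 P with >= 1 P by a specialist in 1 YR),55,7403,14,28,1.1,80,70,89,100,100,100,66,56,76,100,100,100
adults,h1_p2_spec_2y,1H | 2P(spec>=1)/2y,(1 H ever) OR (2 P with >= 1 P by a specialist in 2 YR),55,7403,14,28,1.1,80,70,89,100,100,100,66,56,76,100,100,100
adults,h1_p2_spec_3y,1H | 2P(spec>=1)/3y,(1 H ever) OR (2 P with >= 1 P by a specialist in 3 YR),55,7400,14,31,1.1,80,70,89,100,99,100,64,54,74,100,100,100
adults,h1_p3_spec_1y,1H | 3P(spec>=1)/1y,(1 H ever) OR (3 P with >=1 P by a specialist in 1 YR),54,7417,15,14,0.9,78,69,88,100,100,100,79,70,89,100,100,100
adults,h1_p3_spec_2y,1H | 3P(spec>=1)/2y,(1 H ever) OR (3 P with >=1 P by a specialist in 2 YR),54,7416,15,15,0.9,78,69,88,100,100,100,78,69,88,100,100,100
adults,h1_p3_spec_3y,1H | 3P(spec>=1)/3y,(1 H ever) OR (3 P with >=1 P by a specialist in 3 YR),54,7416,15,15,0.9,78,69,88,100,100,100,78,69,88,100,100,100
adults,h1_p2_gap8w_2y,1H | 2P(gap>=56d)/2y,(1 H ever) OR (2 P >= 8 weeks apart in 2 YR) no exclusions,57,7378,12,53,1.5,83,74,92,99,99,100,52,43,61,100,100,100
adults,h1_p2_gap8w_2y_exAB,"1H | 2P(gap>=56d)/2y excl(A,B)",(1 H ever) OR (2 P >= 8 weeks apart in 2 YR) excluding Case A or Case B,41,7401,28,30,0.9,59,48,71,100,100,100,58,46,69,100,100,100
adults,h1_p2_gap8w_3y_exAB,"1H | 2P(gap>=56d)/3y excl(A,B)",(1 H ever) OR (2 P >= 8 weeks apart in 3 YR) excluding Case A or Case B,41,7396,28,35,1.0,59,48,71,100,99,100,54,43,65,100,100,100
adults,h1_p2_gap8w_4y_exAB,"1H | 2P(gap>=56d)/4y excl(A,B)",(1 H ever) OR (2 P >= 8 weeks apart in 4 YR) excluding Case A or Case B,43,7394,26,37,1.1,62,51,74,100,99,100,54,43,65,100,100,100
adults,h1_p2_gap8w_5y_exAB,"1H | 2P(gap>=56d)/5y excl(A,B)",(1 H ever) OR (2 P >= 8 weeks apart in 5 YR) excluding Case A or Case B,44,7390,25,41,1.1,64,52,75,99,99,100,52,41,62,100,100,100
adults,h1_p2_gap8w_2y_exA,1H | 2P(gap>=56d)/2y excl(A),(1 H ever) OR (2 P >= 8 weeks apart in 2 YR) excluding Case A,41,7402,28,29,0.9,59,48,71,100,100,100,59,47,70,100,100,100
seniors,p1_rx,1P(rx>=1),1 P AND >=1 Rx ever,53,3248,10,115,4.9,84,75,93,97,96,97,32,25,39,100,100,100
seniors,p2_rx,2P(rx>=1),2 P AND >=1 Rx ever,51,3318,12,45,2.8,81,71,91,99,98,99,53,43,63,100,99,100
seniors,p2_gap60_rx,"2P(gap>=60d,rx>=1)",2 P >= 60 days apart AND >=1 Rx ever,49,3320,14,43,2.7,78,68,88,99,98,99,53,43,64,100,99,100
seniors,h1_p2_rx_1y,1H | 2P(rx>=1)/1y,(1 H ever) OR (2 P AND >=1 Rx in 1 YR),52,3337,11,26,2.3,83,73,92,99,99,100,67,56,77,100,100,100
seniors,h1_p2_rx_2y,1H | 2P(rx>=1)/2y,(1 H ever) OR (2 P AND >=1 Rx in 2 YR),52,3335,11,28,2.3,83,73,92,99,99,100,65,55,76,100,100,100
seniors,h1_p2_rx_3y,1H | 2P(rx>=1)/3y,(1 H ever) OR (2 P AND >=1 Rx in 3 YR),52,3332,11,31,2.4,83,73,92,99,99,99,63,52,73,100,100,100
seniors,h1_p2_spec_rx_1y,"1H | 2P(spec>=1,rx>=1)/1y",(1 H ever) OR (2 P with >= 1 P by specialist AND >=1 Rx in 1 YR),52,3347,11,16,2.0,83,73,92,100,99,100,77,66,87,100,100,100
seniors,h1_p2_spec_rx_2y,"1H | 2P(spec>=1,rx>=1)/2y",(1 H ever) OR (2 P with >= 1 P by specialist AND >=1 Rx in 2 YR),52,3346,11,17,2.0,83,73,92,100,99,100,75,65,86,100,100,100
seniors,h1_p2_spec_rx_3y,"1H | 2P(spec>=1,rx>=1)/3y",(1 H ever) OR (2 P with >= 1 P by specialist AND >= 1 Rx in 3 YR),52,3345,11,18,2.0,83,73,92,100,99,100,74,64,85,100,100,100
seniors,h1_p3_rx_1y,1H | 3P(rx>=1)/1y,(1 H ever) OR (3 P AND >= 1 Rx in 1 YR),47,3346,16,17,1.9,75,64,85,100,99,100,73,63,84,100,99,100
seniors,h1_p3_rx_2y,1H | 3P(rx>=1)/2y,(1 H ever) OR (3 P AND >= 1 Rx in 2 YR),48,3342,15,21,2.0,76,66,87,99,99,100,70,59,80,100,99,100
seniors,h1_p3_rx_3y,1H | 3P(rx>=1)/3y,(1 H ever) OR (3 P AND >= 1 Rx in 3 YR),48,3342,15,21,2.0,76,66,87,99,99,100,70,59,80,100,99,100
seniors,h1_p3_spec_rx_1y,"1H | 3P(spec>=1,rx>=1)/1y",(1 H ever) OR (3 P with >= 1 P by specialist AND >= 1 Rx in 1 YR),47,3351,16,12,1.7,75,64,85,100,99,100,80,69,90,100,99,100
seniors,h1_p3_spec_rx_2y,"1H | 3P(spec>=1,rx>=1)/2y",(1 H ever) OR (3 P with >= 1 P by specialist AND >= 1 Rx in 2 YR),48,3349,15,14,1.8,76,66,87,100,99,100,77,67,88,100,99,100
seniors,h1_p3_spec_rx_3y,"1H | 3P(spec>=1,rx>=1)/3y",(1 H ever) OR (3 P with >= 1 P by specialist AND >= 1 Rx in 3 YR),48,3348,15,15,1.8,76,66,87,100,99,100,76,66,87,100,99,100
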