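compound_id,enzyme,kinact_over_KI,censored,bound
2,HNE,160000,FALSE,NA
27,HNE,229000,FALSE,NA
29,HNE,35800,FALSE,NA
62,HNE,227200,FALSE,NA
65,HNE,209000,FALSE,NA
70,HNE,125250,FALSE,NA
75,HNE,304300,FALSE,NA
77,HNE,773400,FALSE,NA
78,HNE,1626200,FALSE,NA
79,HNE,743300,FALSE,NA
80,HNE,81780,FALSE,NA
100,HNE,101800,FALSE,NA
111,HNE,2319700,FALSE,NA
113,HNE,4236800,FALSE,NA
111,PR3,4105900,FALSE,NA
113,PR3,8951600,FALSE,NA
2,CatG,NA,TRUE,50
27,CatG,NA,TRUE,50
29,CatG,NA,TRUE,50
62,CatG,NA,TRUE,50
75,CatG,NA,TRUE,50
77,CatG,NA,TRUE,50
78,CatG,NA,TRUE,50
79,CatG,NA,TRUE,50
111,CatG,NA,TRUE,50
113,CatG,NA,TRUE,50
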