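taxon,mm_pda01,mm_pda02,mm_pda03,mm_pda04,mm_pda05,mm_pda06,mm_pda07,mm_pda08,mm_pda09,mm_pda10,mm_mmn01,mm_mmn02,mm_mmn03,mm_mmn04,mm_mmn05,mm_mmn06,mm_mmn07,mm_mmn08,mm_mmn09,mm_mmn10,mm_ma01,mm_ma02,mm_ma03,mm_ma04,mm_ma05,mm_ma06,mm_ma07,mm_ma08,mm_ma09,mm_ma10,phys01,phys02,phys03,phys04,phys05,phys06,phys07,phys08
!type,unordered,unordered,unordered,unordered,ordered,unordered,unordered,unordered,unordered,unordered,unordered,unordered,ordered,ordered,unordered,unordered,unordered,unordered,unordered,ordered,unordered,unordered,unordered,unordered,unordered,unordered,ordered,unordered,unordered,ordered,unordered,unordered,unordered,unordered,unordered,unordered,unordered,unordered
!partition,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,macromorphology,physiology,physiology,physiology,physiology,physiology,physiology,physiology,physiology
A,1,0,1,0,2,0,0,1,1,0,0,0,2,2,0,1,0,1,0,2,?,0,0,0,0,1,0,0,0,0,1,1,0,1,1,1,0,0
A1,1,0,1,0,2,0,0,1,1,0,0,0,2,2,0,1,0,1,0,2,0,0,0,0,0,0,0,0,0,0,1,1,0,1,1,1,0,0
F,1,0,1,0,2,0,0,1,1,0,0,0,2,2,0,0,0,1,0,2,0,0,1,0,0,0,0,0,0,0,1,1,0,1,1,1,0,0
B2,0,1,1,0,1,0,0,0,0,1,0,0,0,1,1,0,0,1,0,2,0,0,0,0,0,0,2,0,0,0,0,1,0,0,1,1,0,0
D2,0,1,1,0,1,0,0,0,0,1,0,0,0,1,1,0,0,1,0,2,0,0,0,?,0,0,0,1,0,0,0,1,0,0,1,1,0,1
B1,0,0,0,1,0,0,1,0,0,0,1,0,0,0,1,0,0,1,0,2,0,0,0,1,0,0,0,0,0,0,0,0,1,0,1,1,0,0
D1,0,0,0,1,0,0,1,0,0,0,0,1,0,0,1,0,0,1,0,2,0,0,0,0,1,0,0,0,0,0,0,0,1,0,1,1,0,0
C,0,0,0,1,0,1,0,1,0,0,1,0,0,0,0,0,0,1,0,2,0,1,0,0,0,0,0,0,0,0,0,0,0,1,1,1,0,0
E,0,0,0,1,0,1,0,1,0,0,0,1,0,0,0,0,0,1,0,2,1,0,0,0,0,0,0,0,0,3,0,0,0,1,1,1,1,0
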