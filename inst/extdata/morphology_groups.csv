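morphology_code,subtype,leukemia_excl_cll,therapy_related
9650,HL,FALSE,FALSE
9651,HL,FALSE,FALSE
9652,HL,FALSE,FALSE
9653,HL,FALSE,FALSE
9655,HL,FALSE,FALSE
9659,HL,FALSE,FALSE
9661,HL,FALSE,FALSE
9663,HL,FALSE,FALSE
9665,HL,FALSE,FALSE
9667,HL,FALSE,FALSE
9673,mature_B,FALSE,FALSE
9679,mature_B,FALSE,FALSE
9680,mature_B,FALSE,FALSE
9684,mature_B,FALSE,FALSE
9687,mature_B,FALSE,FALSE
9689,mature_B,FALSE,FALSE
9690,mature_B,FALSE,FALSE
9691,mature_B,FALSE,FALSE
9695,mature_B,FALSE,FALSE
9698,mature_B,FALSE,FALSE
9699,mature_B,FALSE,FALSE
9761,mature_B,FALSE,FALSE
9823,mature_B,FALSE,FALSE
9833,mature_B,TRUE,FALSE
9940,mature_B,TRUE,FALSE
9700,mature_TNK,FALSE,FALSE
9701,mature_TNK,FALSE,FALSE
9702,mature_TNK,FALSE,FALSE
9705,mature_TNK,FALSE,FALSE
9714,mature_TNK,FALSE,FALSE
9716,mature_TNK,FALSE,FALSE
9717,mature_TNK,FALSE,FALSE
9718,mature_TNK,FALSE,FALSE
9719,mature_TNK,FALSE,FALSE
9726,mature_TNK,FALSE,FALSE
9768,mature_TNK,FALSE,FALSE
9827,mature_TNK,TRUE,FALSE
9831,mature_TNK,TRUE,FALSE
9834,mature_TNK,TRUE,FALSE
9948,mature_TNK,TRUE,FALSE
9727,precursor,FALSE,FALSE
9728,precursor,FALSE,FALSE
9729,precursor,FALSE,FALSE
9811,precursor,TRUE,FALSE
9812,precursor,TRUE,FALSE
9813,precursor,TRUE,FALSE
9814,precursor,TRUE,FALSE
9815,precursor,TRUE,FALSE
9816,precursor,TRUE,FALSE
9817,precursor,TRUE,FALSE
9818,precursor,TRUE,FALSE
9835,precursor,TRUE,FALSE
9836,precursor,TRUE,FALSE
9837,precursor,TRUE,FALSE
9590,NHL_NOS,FALSE,FALSE
9591,NHL_NOS,FALSE,FALSE
9596,NHL_NOS,FALSE,FALSE
9820,lymphoid_NOS,TRUE,FALSE
9840,AML_ALMP_ALAL,TRUE,FALSE
9861,AML_ALMP_ALAL,TRUE,FALSE
9865,AML_ALMP_ALAL,TRUE,FALSE
9866,AML_ALMP_ALAL,TRUE,FALSE
9867,AML_ALMP_ALAL,TRUE,FALSE
9869,AML_ALMP_ALAL,TRUE,FALSE
9871,AML_ALMP_ALAL,TRUE,FALSE
9872,AML_ALMP_ALAL,TRUE,FALSE
9873,AML_ALMP_ALAL,TRUE,FALSE
9874,AML_ALMP_ALAL,TRUE,FALSE
9891,AML_ALMP_ALAL,TRUE,FALSE
9895,AML_ALMP_ALAL,TRUE,FALSE
9896,AML_ALMP_ALAL,TRUE,FALSE
9897,AML_ALMP_ALAL,TRUE,FALSE
9898,AML_ALMP_ALAL,TRUE,FALSE
9910,AML_ALMP_ALAL,TRUE,FALSE
9911,AML_ALMP_ALAL,TRUE,FALSE
9931,AML_ALMP_ALAL,TRUE,FALSE
9805,AML_ALMP_ALAL,TRUE,FALSE
9806,AML_ALMP_ALAL,TRUE,FALSE
9807,AML_ALMP_ALAL,TRUE,FALSE
9808,AML_ALMP_ALAL,TRUE,FALSE
9809,AML_ALMP_ALAL,TRUE,FALSE
9863,MPN_MDS,TRUE,FALSE
9875,MPN_MDS,TRUE,FALSE
9876,MPN_MDS,TRUE,FALSE
9945,MPN_MDS,TRUE,FALSE
9946,MPN_MDS,TRUE,FALSE
9950,MPN_MDS,FALSE,FALSE
9960,MPN_MDS,FALSE,FALSE
9961,MPN_MDS,FALSE,FALSE
9962,MPN_MDS,FALSE,FALSE
9963,MPN_MDS,FALSE,FALSE
9964,MPN_MDS,FALSE,FALSE
9975,MPN_MDS,FALSE,FALSE
9980,MPN_MDS,FALSE,FALSE
9982,MPN_MDS,FALSE,FALSE
9983,MPN_MDS,FALSE,FALSE
9985,MPN_MDS,FALSE,FALSE
9986,MPN_MDS,FALSE,FALSE
9989,MPN_MDS,FALSE,FALSE
9800,myeloid_NOS,TRUE,FALSE
9801,myeloid_NOS,TRUE,FALSE
9860,myeloid_NOS,TRUE,FALSE
9750,histiocytic,FALSE,FALSE
9751,histiocytic,FALSE,FALSE
9755,histiocytic,FALSE,FALSE
9756,histiocytic,FALSE,FALSE
9757,histiocytic,FALSE,FALSE
9758,histiocytic,FALSE,FALSE
8000,unspecified,FALSE,FALSE
9920,AML_ALMP_ALAL,TRUE,TRUE
9987,MPN_MDS,FALSE,TRUE
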