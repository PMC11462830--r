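variable,level,non_recurrence,recurrence,printed_p
gender,male,14,10,0.971
gender,female,11,13,0.971
midline_invasion,yes,7,6,0.882
midline_invasion,no,18,17,0.882
lesion_location,frontal,11,12,0.571
lesion_location,non_frontal,14,11,0.571
lesion_size,lt6cm,9,13,0.154
lesion_size,ge6cm,16,10,0.154
lesion_margin,sharp,19,9,0.010
lesion_margin,blurred,6,14,0.010
histology,astrocytoma,18,16,0.309
histology,oligodendroglioma,3,6,0.309
histology,unclear,4,1,0.309
grading,II,11,17,0.020
grading,III,14,5,0.020
therapy,chemo_radio,10,16,0.428
therapy,chemo,2,1,0.428
therapy,radio,7,5,0.428
therapy,not_clear,6,3,0.428
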