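# provenance: Live surgical measurements of the Oyster toadfish labyrinth; means of 12-25 measurements from 3-5 fish with individual max/min; utricle measured at its narrowest point.
"chamber","shape_model","w_mean","w_max","w_min","r_mean","r_max","r_min","a","b","r_tube","R_loop"
"Anterior Canal","cylinder",70,86,45,307,322,270,,,,
"Lateral Ampulla","sphere",58,75,44,697,788,625,,,,
"Utricle","cylinder",32,42,20,556,654,469,,,,
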