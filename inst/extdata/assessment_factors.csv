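rule_id,description,af
1-acute,1 trophic acute level,10000
2-acute,2 trophic acute levels (most sensitive taxon),5000
3-acute,3 trophic acute levels (most sensitive taxon),1000
3-acute+1-chronic-other,3 trophic acute levels and 1 chronic datum not on the most sensitive acute taxon,1000
3-acute+1-chronic-ms,3 trophic acute levels and 1 chronic datum on the most sensitive acute taxon,100
3-acute+2-chronic-ms,3 trophic acute levels and 2 chronic data including the most sensitive acute taxon,50
3-acute+3-chronic,3 trophic acute levels and 3 chronic levels,10
gt10-chronic,more than 10 chronic toxicity data or microcosm/mesocosm studies,5
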