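cross_id,crossing_date,germinated_diploid,germinated_haploid,ungerminated_aborted
1,2023-07-02,101,25,37
2,2023-08-31,71,19,18
3,2023-08-31,42,15,9
4,2023-09-11,83,16,7
5,2023-09-15,44,9,21
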