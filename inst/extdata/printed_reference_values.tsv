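rag_id	printed_lambda2	printed_abs_mu2
2_1	NA	NA
3_1	NA	NA
4_1	NA	NA
4_2	NA	NA
5_2	NA	NA
6_1	0.27	0.56,0.41,0.15,0.15,0.41,0.56
6_2	0.32	0.42,0.28,0.42,0.08,0.42,0.62
6_5	0.49	0.32,0.16,0.32,0.38,0.73,0.32
10_19	NA	NA
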