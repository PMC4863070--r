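subject_id,pre_vo2,post_vo2,system_pre,system_post
s01,1.52,1.68,parvo_2400,parvo_2400
s02,2.10,2.31,parvo_2400,parvo_2400
s03,2.85,2.79,parvo_2400,parvo_2400
s04,3.28,3.52,douglas_bag,douglas_bag
s05,3.01,3.33,douglas_bag,parvo_2400
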