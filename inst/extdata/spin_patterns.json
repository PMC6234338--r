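["000000011","000000110","000001100","000001101","000001110","000001111","000010011","000010110","000011100","000011101","000011110","000011111","000100001","000100011","000100101","000100111","000101001","000101011"]
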