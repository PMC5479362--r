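"variable","type"
"B","discrete"
"F","discrete"
"W","discrete"
"C","continuous"
"E","continuous"
"MW","continuous"
"D","continuous"
"L","continuous"
"ME","continuous"
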