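label,years
never went to school,0
8th grade or less,8
"more than eighth grade, but did not graduate from high school",10
"went to a business, trade, or vocational school instead of high school",10
high school graduate,12
completed a GED,12
"went to a business, trade, or vocational school after high school",14
"went to college, but did not graduate",14
graduated from a college or university,16
professional training beyond a four-year college or university,18
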