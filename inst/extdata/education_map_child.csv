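label,years
8th grade or less,8
some high school,10
high school graduate,12
some vocational/technical training,13
completed vocational/technical training,14
some college,14
completed college,16
some graduate school,17
completed a master's degree,18
some graduate training beyond a master's degree,19
completed a doctoral degree,20
some post-baccalaureate professional education,18
completed post-baccalaureate professional education,19
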