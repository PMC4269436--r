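# Real season files (optional, user-supplied)

Place full-season game files here to run the package's league
reproductions, e.g.:

    nfl2013.csv   nfl2012.csv   epl2012-13.csv   epl2011-12.csv

Expected layout: the canonical comma-separated dialect with header
`round,team_a,score_a,team_b,score_b` (any other delimited layout can be
converted via `read_games()` + `write_games()` with a custom
`game_dialect()`). No real league data is redistributed with the package.
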