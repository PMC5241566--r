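# Visual and computed grades for the supra-centimetric lung lesions with
# grade above 0 in a first-in-human In-111 radiolabelled-antibody study
# (19 lesions across 8 patients). "lower" in the note column marks lesions
# whose computed grade fell below the visual grade; exactly five such
# discordant lesions exist, all others are concordant.
#
# Reading notes for rows garbled in transcription:
#   - patient 11, lesion 1: visual IV / computed II (the single large
#     visual-computed difference in this lesion set).
#   - patient 15, lesion 1: the grade pair is typographically truncated
#     ("III"); read as the concordant pair II/II, consistent with the
#     set's count of five discordant lesions, all of which carry a
#     "lower grade" annotation.
patient,lesion,visual,computed,note
5,1,I,I,
5,2,III,III,
8,1,III,III,
8,2,III,III,
8,3,IV,IV,
8,4,IV,III,lower
10,1,III,II,lower
10,2,II,II,
10,3,II,II,
10,4,I,I,
11,1,IV,II,lower
11,2,I,I,
11,3,II,I,lower
11,4,I,I,
11,5,I,I,
15,1,II,II,garbled in source; concordant reading
17,1,II,II,
20,1,III,III,
20,2,III,II,lower
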