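# Default ITS domain templates. kind: motif = fixed-length IUPAC match;
# terminal_motif = anchor match extending to the ITS 3' end; helix =
# stem-loop fold specification (stem/loop length ranges; max_start bounds
# the helix start relative to the search origin). The D3 variants and the
# ITS start are fixed by comparative evidence for the study group; the
# remaining motifs are synthetic placeholders that users should replace
# with organism-specific templates.
domain	kind	pattern	required
D1-D1'	helix	stem=6:8,loop=4:6,max_start=40	yes
D2	motif	GAAGGCATCAGGC	yes
D3	motif	GGTWY	yes
tRNA-Ile	motif	GGGCTATTAGCTCAGTTGGTTAGAGC	no
V2	helix	stem=4:5,loop=3:5	no
tRNA-Ala	motif	GGGGCCTTAGCTCAGCTGGGAGAGC	no
BoxB	helix	stem=5:7,loop=3:6	yes
BoxA	motif	GCTCTTTAACAA	yes
D4	motif	AGKTCAGCRTW	yes
V3	helix	stem=5:6,loop=4:6	yes
D5	terminal_motif	GGATCW	yes
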