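# Bundled example data

`vlinc273_region_rmsk_synthetic.out` — a **synthetic** RepeatMasker-format
annotation of a 185 kb window on chromosome 6 (140,730,001–140,915,000,
~141 Mb). It is generated, not downloaded: repeat fragments are placed so
that the merged LINE/L1 coverage of the window is exactly 0.29 of its
length, with roughly two thirds of L1 fragments in the antisense (`C`)
orientation and a sprinkling of Alu/MIR/L2/DNA/LTR elements between them.
It stands in for the real RepeatMasker annotation of an L1-rich vlincRNA
locus in worked examples and tests of the `.out` reader and the
repeat-composition code path; it is not a copy of any reference annotation.
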