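# Causal trinucleotide channels for BRAF driver mutation classes.
# coding_context is the trinucleotide around the mutated base on the BRAF
# coding strand (BRAF is transcribed from the genomic minus strand, so
# reference-strand contexts are the reverse complements of these; the
# pyrimidine collapse makes the channel strand-invariant).
# Contexts come from the canonical BRAF kinase-domain coding sequence:
# codons 461-476 CAA AGA ATT GGA TCT GGA TCA TTT GGA ACA GTC TAC AAG GGA ...
#   (Q461 R462 I463 G464 S465 G466 S467 F468 G469 T470 V471 Y472 K473 G474)
# codons 581-602 AAT ATA TTT CTT CAT GAA GAC CTC ACA GTA AAA ATA GGT GAT
#   TTT GGT CTA GCT ACA GTG AAA TCT
#   (N581 I582 F583 L584 H585 E586 D587 L588 T589 V590 K591 I592 G593 D594
#    F595 G596 L597 A598 T599 V600 K601 S602)
# channel must equal the pyrimidine collapse of (coding_context, ref, alt);
# this is re-verified at load time. Edit rows to change the causal sets.
class	protein_change	cdna_change	coding_context	coding_ref	coding_alt	channel
class1	V600E	c.1799T>A	GTG	T	A	G[T>A]G
class2	G464V	c.1391G>T	GGA	G	T	T[C>A]C
class2	G464E	c.1391G>A	GGA	G	A	T[C>T]C
class2	G469V	c.1406G>T	GGA	G	T	T[C>A]C
class2	G469A	c.1406G>C	GGA	G	C	T[C>G]C
class2	G469R	c.1405G>A	TGG	G	A	C[C>T]A
class2	L597V	c.1789C>G	TCT	C	G	T[C>G]T
class2	L597Q	c.1790T>A	CTA	T	A	C[T>A]A
class2	K601E	c.1801A>G	GAA	A	G	T[T>C]C
class3	G466V	c.1397G>T	GGA	G	T	T[C>A]C
class3	G466E	c.1397G>A	GGA	G	A	T[C>T]C
class3	G466A	c.1397G>C	GGA	G	C	T[C>G]C
class3	N581S	c.1742A>G	AAT	A	G	A[T>C]T
class3	N581I	c.1742A>T	AAT	A	T	A[T>A]T
class3	D594G	c.1781A>G	GAT	A	G	A[T>C]C
class3	D594N	c.1780G>A	TGA	G	A	T[C>T]A
class3	D594H	c.1780G>C	TGA	G	C	T[C>G]A
class3	F595L	c.1783T>C	TTT	T	C	T[T>C]T
class3	F595L	c.1785T>A	TTG	T	A	T[T>A]G
class3	G596R	c.1786G>C	TGG	G	C	C[C>G]A
class3	G596D	c.1787G>A	GGT	G	A	A[C>T]C
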