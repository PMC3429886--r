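# cgrphylo

Alignment-free phylogenetics from Chaos Game Representations of nucleotide
sequences.

Whole-genome, EST and organellar datasets of higher eukaryotes are too large
and too rearranged for multiple sequence alignment, yet their oligonucleotide
composition — the *genomic signature* — is similar across the sub-sequences of
one genome and discriminates between genomes. `cgrphylo` turns that signature
into trees:

1. **CGR.** A sequence is plotted inside the unit square with vertices
   C (upper left), G (upper right), A (lower left), T (lower right). Starting
   from the centre, CGR₀ = (0.5, 0.5), each base moves the point halfway
   toward its vertex: CGRᵢ = (CGRᵢ₋₁ + vertex(seqᵢ)) / 2. The point cloud is
   a unique fingerprint of the sequence.
2. **FCGR.** Dividing the square into a 2ᵏ × 2ᵏ grid and counting points per
   cell gives the Frequency CGR: cell (r, c) holds the occurrence count of
   one specific k-mer. `cgrphylo` computes this by exact k-mer counting
   (identical to binning the CGR points from step k on, but immune to float
   drift). To remove sequence-length bias the matrix A is standardized to
   Ā = (4ᵏ / Σᵢⱼ aᵢⱼ) · A, so cells average 1.
3. **Distances.** Between two taxa: the Euclidean distance
   d = (2ᵏ/4ᵏ) · √Σᵢⱼ(āᵢⱼ − b̄ᵢⱼ)² on standardized FCGRs, or a weighted
   Pearson distance d = 1 − r_w ∈ [0, 2] on raw counts, where each cell pair
   is weighted by xᵢyᵢ / Σxᵢyᵢ.
4. **Trees.** Neighbor-Joining on the distance matrix; branch support from a
   bootstrap that resamples the 4ᵏ FCGR cells with replacement (one shared
   index vector per replicate across all taxa — the cells play the role of
   characters in the classical taxon-by-character bootstrap); majority-rule
   consensus; and Fitch–Margoliash-style weighted least-squares branch
   lengths (weights 1/d²) fitted on the fixed consensus topology.

Per-taxon input is a multi-record FASTA (contigs, EST reads, or an organelle
genome). Records are concatenated, characters outside {A,C,G,T} deleted, and
the reverse complement of the concatenation appended, making the k-mer
spectrum strand-symmetric. For EST data the two FCGR cells holding the
A…A/T…T homopolymers are zeroed before any distance is computed: untrimmed
poly-A tails otherwise dominate high-resolution (k > 5) distance matrices
and misdirect the trees.

The package also ships a simulator (random composition-controlled sequences,
random additive trees with exact path-length matrices, sequence evolution
along a known tree) so every claim above is testable against a known truth,
plus SVG/PGM/PNG renderings of CGRs and FCGRs and PHYLIP/Newick interchange.

## Worked example

Simulate eight taxa in two clades along a known tree, then run the full
pipeline at k = 6 with the Euclidean metric and 100 bootstrap replicates:

```r
library(cgrphylo)

truth <- two_clade_tree()                 # ((A,B),(C,D)) | ((E,F),(G,H))
scn   <- sim_scenario(truth, root_length = 20000, seed = 42)
taxa  <- write_taxa_fasta(evolve_sequences(scn), "example_fastas",
                          n_records = 5)
cfg   <- run_config(taxa, k = 6, metric = "euclidean",
                    replicates = 100, seed = 42)
res   <- run_pipeline(cfg)
print(res)
#> BootstrapResult: 8 taxa, k=6, euclidean, 100 replicates (0 redrawn)
#> consensus: (A:0.149949,B:0.158587,((C:0.159627,D:0.153751)100:0.0318632,((E:0.156532,F:0.148758)100:0.0369773,(G:0.156137,H:0.147724)100:0.0407726)100:0.0633108)100:0.0327925);
robinson_foulds(res$consensus, truth)
#> [1] 0
```

Every internal edge of the consensus carries its bootstrap percentage (here
100 throughout), branch lengths are the weighted least-squares fit on the
fixed consensus topology, and the topology matches the generating tree
(Robinson–Foulds distance 0). Individual building blocks are exported too:

```r
f <- compute_fcgr(build_dataset_sequence(read_fasta(taxa$path[1]), "A"), 3)
print(f)
#> FCGR k=3 (8x8 cells), raw counts, source length 40000 nt
round(standardize_fcgr(f)$cells[1:4, 1:4], 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 1.011 0.954 1.074 0.954
#> [2,] 1.016 1.029 0.979 1.019
#> [3,] 0.986 1.051 0.979 1.051
#> [4,] 1.005 0.981 0.986 0.994
```

Cell indices are 0-based image coordinates: row 0 is the top of the square,
cell (row, col) of the 2ᵏ grid is the k-mer whose i-th base contributes
2^(i−1) to col if it is G/T and to row if it is A/T (so "CG" sits at (0, 2),
poly-A at the bottom-left corner, poly-T at the bottom-right).

A thin command-line front end with subcommands `fcgr`, `distmat`, `tree`,
`bootstrap` and `shred` is installed at `cli/cgrphylo.R` inside the package
directory:

```sh
Rscript "$(Rscript -e 'cat(find.package("cgrphylo"))')/cli/cgrphylo.R" \
  bootstrap --taxa taxa.tsv --k 6 --metric euclidean \
  --replicates 500 --seed 1 --outdir run/
```

## Scope

The package reconstructs distance trees from FCGRs; it does not perform
alignment-based inference (no ML/parsimony, no protein trees), does not
search tree space under the Fitch–Margoliash criterion (least squares is
used only to fit branch lengths on a fixed topology, with Neighbor-Joining
as the search step), and does not fetch any public datasets.
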