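# neovax

Neoantigen prioritization and long vaccine peptide design from
multi-caller somatic variant calls.

## What this is for

Low mutational load tumors (the motivating case is resected pancreatic
ductal adenocarcinoma) carry only a few dozen somatic mutations, too few
and too weakly presented for direct mass-spectrometric neoantigen
detection. Selecting the payload of a personalized peptide vaccine — ten
long synthetic peptides per patient — therefore runs *in silico*: call
somatic variants with several callers, build mutant peptide contexts,
predict HLA class I and class II ligands, filter, and design the shortest
long peptides covering the most predicted epitopes. `neovax` implements
that pipeline for bioinformaticians building or evaluating such antigen
discovery workflows, with a seeded synthetic-cohort generator whose planted
ground truth makes every stage testable without access-controlled patient
data.

## The method in brief

1. **Consensus calls.** Three per-caller VCFs are merged into a
   non-redundant union keyed on `(chrom, pos, ref, alt)`. Conflicting calls
   at one coordinate are resolved by a strict majority of the callers
   reporting there; no majority, no call. Somatic = tumor-only; germline
   evidence from any caller wins. *High confidence* = somatic detected by
   MuTect-style caller alone or by ≥ 2 of 3 callers, plus germline SNPs
   phase-linked (same phase set, same haplotype) to a retained somatic
   variant.
2. **Contexts.** Each missense mutation becomes a 31-mer with the novel
   residue at position 16 (truncated at termini), including linked-SNP
   edits; optionally, a frameshift yields the 24 upstream residues plus the
   novel open-reading-frame translation (off by default).
3. **Binding.** All mutation-spanning 9–12-mers (class I) and 12–19-mers
   (class II) are scored per allele — by the built-in position-weight-matrix
   scorer with decoy-calibrated percentile ranks
   (%Rank = 100 · Pr(decoy ≥ score), p = %Rank/100, N = 100,000 decoys per
   length, fixed seed), or by an external predictor score table. Binder:
   %Rank < 5 for ≥ 1 allele, or exact wild-type match in the ligand
   database.
4. **Filters.** Drop mutations in genes with 90th-percentile tissue
   expression TPM < 1, mutant peptides occurring anywhere in a reference
   proteome, genes with > 3 somatic mutations, and (optionally)
   database-underrepresented source proteins. Wild-type forms are
   classified against immunopeptidome hotspots as
   EXACT / INCLUDED / PARTIAL / NONE.
5. **Design and ranking.** Per mutation, the shortest contiguous context
   window containing the maximum number of fully contained binders;
   mutations ranked by minimum class I p-value, then binder count, allele
   counts, EXACT-match tie-break and genomic coordinate; top 10 reported in
   a fourteen-column table.
6. **Proteogenomics.** A customized FASTA (reference entries plus
   mutation-annotated mutant entries, `tx|gene|p.Ala2Val;...`) and
   mutant/wt/unmapped flags for MS-identified peptides.

## Worked example

Generate a synthetic cohort (single-chromosome toy genome, three caller
VCFs with planted concordance/discordance and phasing, expression table,
ligand database, PWM motifs, ground truth) and run the pipeline:

```r
library(neovax)
spec <- fixtureSpec(seed = 42)          # 23 somatic mutations, 14 genes
generateCohort(spec, "demo")
res <- runPipeline("demo", outDir = "demo/out")
res$report[, c(1:6, 8, 10, 12:14)]
```

```
 Rank Chromosome_position   Gene Expression_TPM_p90                Mutation
    1               1_290 GENE01            33.0707              p.Leu87Trp
    2               1_860 GENE02            36.1493              p.Leu98Trp
    3              1_3671 GENE06            32.9872 p.Leu205Trp+p.Leu198Trp
    4              1_2900 GENE05            30.5591             p.Leu127Trp
    5              1_4049 GENE07            30.7227              p.Ala73Val
 Driver_status ipMSDB_HLA-I Lowest_HLA-I_pval N_predicted_peptides
                      EXACT           0.00008                   63
        Driver     INCLUDED           0.00704                    4
                                      0.00704                    4
                    PARTIAL           0.00704                    3
                      EXACT           1.00000                    1
 N_HLA-I_alleles N_HLA-II_alleles
               1                1
               1                0
               1                0
               1                0
               0                0
```

Reading the rows: the rank-1 mutation is the cohort's engineered best
binder — its long peptide (29 residues,
`AQRFKTNLLAWMRWGSNWMVVYCGGGSCL`) contains 63 distinct predicted epitopes
across both HLA classes and its wild-type forms match the ligand database
exactly. Rank 2 is a driver-gene binder detected by one caller (retained by
the MuTect-alone rule); rank 3 carries a phased linked germline SNP, so its
mutation label lists both edits; rank 4 lost one 9-mer to the wild-type
identity filter (3 binders instead of 4); rank 5 is a non-binder by rank
(p = 1.0) rescued only by an exact wild-type ligand-database match. The
planted expression-filtered, hypermutated-gene and low-confidence mutations
are correctly absent, and `expectedTruth("demo")` exposes the full planted
expectation for every variant.

A thin CLI covering fixture generation and the full run lives at
`inst/scripts/neovax-cli.R`:

```sh
Rscript inst/scripts/neovax-cli.R make-fixtures --dir demo --seed 42
Rscript inst/scripts/neovax-cli.R run-all --dir demo
```

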