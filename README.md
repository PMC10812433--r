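# contactmap

Contact-based analysis of how one receptor protein recognises an ensemble of
protein ligands, from the structures of their complexes.

Small redox hubs such as the mitochondrial thioredoxin use a limited surface
to bind dozens of partner proteins, covalently (transient mixed disulfides)
and non-covalently. Given PDB structures of receptor-ligand complexes plus an
interaction category for each (covalent / strong non-covalent / weak),
`contactmap` answers: *which receptor residues do the binding, how strongly,
and where on the surface are the covalent and non-covalent recognition areas?*

## What it computes

* **Interfacial contacts (ICs)** — cross-interface residue pairs within a
  heavy-atom cutoff (5.5 Å), typed geometrically (hydrogen bond ≤ 3.5 Å,
  salt bridge ≤ 4.0 Å, hydrophobic C–C ≤ 4.5 Å) and tallied by the
  charge-class pair of the residues.
* **Binding affinity** — the contact-based linear model

  ΔG = −(0.09459 IC_cc + 0.10007 IC_ca − 0.19577 IC_pp + 0.22671 IC_pa
  − 0.18681 %NIS_apolar − 0.13810 %NIS_charged + 15.9433) kcal/mol,

  where %NIS is the class composition of the non-interacting (surface,
  non-interface) residues, and K_D = exp(ΔG / RT) at 298.15 K. The global
  sign is negated relative to the printed coefficient set so that realistic
  interfaces give negative ΔG (see the methods vignette); the printed
  orientation is available as `sign_convention = "as_printed"`.
* **Alanine scanning** — side-chain truncation, profile re-computation and
  ΔΔG = ΔG_wt − ΔG_mut; |ΔΔG| > 2 kcal/mol flags a thermodynamic hot spot.
* **Contact hot spots** — per-residue contact frequencies across the
  ensemble (one hit per complex), by interaction category; residues above a
  percentage threshold (default > 1%) are statistical hot spots.
* **Residue networks** — Cα contact graphs (edge if d < 7 Å) and
  energy-weighted graphs (pairwise vdW + screened Coulomb energy within
  0.1–1 kcal/mol), with closeness / betweenness / average-nearest-neighbour
  degree, hydropathy-class subnetworks and "energy neighbours" of seeds.
* **Contact areas** — hot spots ∪ their energy neighbours, partitioned into
  only-covalent / only-strong-non-covalent / common surface regions, and
  projected onto homologous structures by Needleman–Wunsch (BLOSUM62) +
  Kabsch superposition with iterative outlier pruning.
* **Synthetic fixtures** — pegboard complexes with exact planted IC/NIS
  profiles, folds whose Cα graph equals a prescribed graph, and ensembles
  with planted hot spots, so every stage is testable offline.

## Worked example

```r
library(contactmap)

toy <- make_toy_complex(toy_complex_spec(
  ic_counts  = c(cc = 2, ca = 3, pp = 1, pa = 4),
  nis_counts = c(charged = 6, polar = 3, apolar = 3), seed = 5))
prof <- contact_profile(toy$model, "A", "B", sasa_cfg = list(n_points = 480))
prof
#> <interface_contact_profile>
#>   ICs: charged_charged=2 charged_polar=0 charged_apolar=3 polar_polar=1
#>        polar_apolar=4 apolar_apolar=0
#>   %NIS: charged=50.0 polar=25.0 apolar=25.0
#>   contacts: 10 (receptor residues 10, ligand residues 10)

dg <- predict_dG(prof)
sprintf("dG = %.3f kcal/mol, KD = %.3g M", dg, dG_to_KD(dg))
#> "dG = -5.569 kcal/mol, KD = 8.28e-05 M"

ala_scan(toy$model, "A", "B", residues = list(1),
         sasa_cfg = list(n_points = 480))
#>   mutant dg_wt dg_mut     ddg   kd_mut thermo_hotspot
#> 1    H1A -5.57  -5.57 0.00548 8.21e-05          FALSE
```

The measured profile equals the generator's bookkeeping exactly (2 + 3 + 1 +
4 = 10 contacts; the 12 extra surface residues split 6/3/3 give NIS
50/25/25%). Mutating the His that carries one charged/charged contact turns
it into a charged/apolar contact, so ΔΔG = −(w_ca − w_cc) = 0.0055 kcal/mol —
far below the 2 kcal/mol hot-spot threshold.

Reference conversions: ΔG of −12.3, −12.1 and −10.2 kcal/mol correspond to
K_D ≈ 0.96, 1.3 and 33 nM at 298.15 K; with 13 available hot-spot positions
and 7 used per ligand there are C(13,7) = 1716 distinct binding fingerprints.

## Full pipeline

```r
run_pipeline(list(
  complexes = list(list(path = "complex1.pdb", receptor_chains = "A",
                        ligand_chains = "B", category = "covalent")),
  out_dir = "out"))
```

writes `profiles.tsv` (ICs, %NIS, ΔG, K_D per complex), `frequency.tsv`
(per-residue hit counts, percentages and hot-spot flags per category),
network edge lists, `centralities.tsv`, `areas.tsv` +
`areas_annotations.tsv` (chain/resnum/label) and a `summary.json` echoing
every threshold in effect. A thin CLI (`inst/scripts/contactmap`) exposes
`run` and `simulate` subcommands.

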