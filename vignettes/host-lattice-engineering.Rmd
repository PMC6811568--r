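---
title: "Engineering host:guest crystal lattices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering host:guest crystal lattices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostlattice)
```

## The problem

Crystallising an arbitrary protein is the slowest and least predictable step
of macromolecular crystallography. One way around it is host-lattice
display: a scaffold ("auxiliary") protein that crystallises reliably, with
very large solvent channels, is fused rigidly to a binder domain (for
example a designed ankyrin repeat protein, DARPin). The binder recruits the
molecule of interest — the guest — into a predefined position in the host
crystal, so the guest structure can be solved from difference density
without a new crystallisation campaign.

`hostlattice` implements the desk-scale computations of that engineering
workflow: screening candidate host lattices, crystal symmetry expansion,
crystal-contact accounting, rigid shared-helix fusion with rotational
enumeration, disulfide-crosslink scanning across symmetry mates, guest
cavity sizing, and rigidity analytics.

## Host screening: the Matthews coefficient

A usable host must combine an unusually high solvent content with good
diffraction. The solvent content of a crystal form follows from the
Matthews coefficient

$$V_M = \frac{V_{cell}}{Z \cdot M_w} \qquad
  \phi_{solv} = 1 - \frac{1.66\,\bar v}{V_M},$$

with $V_{cell}$ the unit-cell volume (Å³), $Z$ the number of molecules per
cell (space-group multiplicity × molecules per asymmetric unit), $M_w$ the
molecular weight (Da) and $\bar v$ the protein partial specific volume.
We use the classic $\bar v = 0.74$ cm³/g (so $\phi_{solv} = 1 -
1.2284/V_M$), which maps a host with $V_M = 4.38$ Å³/Da to 72% solvent:

```{r}
100 * solvent_fraction(4.38)
```

`screen_hosts()` filters a candidate table by $V_M \ge$ `min_vm` and
resolution $\le$ `max_res` and ranks by $V_M$ (ties: resolution, then
accession). The defaults `min_vm = 4.3` Å³/Da and `max_res = 2.0` Å are the
tightest bounds that retain all eight reference candidates shipped in
`inst/extdata/host_candidates.csv`; the filter uses non-strict
inequalities, so a candidate sitting exactly on a threshold is kept.

```{r}
screen_hosts(read_host_table(system.file("extdata", "host_candidates.csv",
                                         package = "hostlattice")))
```

## Crystal frames, operators and symmetry expansion

`unit_cell()` validates positive lengths, angles in (0°, 180°) and a
positive-definite metric; `frac_cart_transform()` uses the standard
convention (*a* along x, *b* in the xy-plane) and `cell_volume()` the
triclinic closed form. Symmetry operators are stored as an integer rotation
matrix in the fractional basis plus an *un-normalised* translation: an
operator printed as `x-y,x,z+5/6` and its lattice translate `x-y,x,z-1/6`
keep distinct translations, because contact tables distinguish exactly such
variants. `reduce_symop()` splits off the integer lattice shift when a
canonical coset representative is needed. Translations in the supported
groups are multiples of 1/12, so compositions are snapped to a 1/12 grid,
which makes group closure exact rather than tolerance-based.

Space groups come from an embedded generator table covering the chiral
groups a protein crystallographer typically meets (`P1` through `P6522`;
see `supported_space_groups()`). The full coset list is generated by
breadth-first closure of the generators and checked against the known
multiplicity at construction time.

`expand_neighbors()` enumerates symmetry mates with lattice shifts in
$[-2, 2]^3$ (sufficient for any cutoff up to about the cell edge), with a
bounding-box rejection before the all-pairs distance check. Cutoffs larger
than twice the cell diagonal are refused unless forced, to catch runaway
expansions. The test suite verifies the result against a shortcut-free
brute-force enumeration on small cells.

## Crystal contacts and surface areas

Solvent-accessible surface areas use Shrake–Rupley sampling with a
deterministic golden-section spiral point set (default 960 points/atom,
probe 1.4 Å; van der Waals radii C 1.70, N 1.55, O 1.52, S/P 1.80 Å,
default 1.70 Å). There is deliberately no randomness: a given input always
yields the same area. Buried interface area follows the single-interface
convention

$$A_{buried} = \tfrac{1}{2}\left(SASA(A) + SASA(B) - SASA(A \cup B)\right),$$

with hydrogens always excluded and waters/ligands excluded by default
(contact tables account for polypeptide chains). Note that any finite
point sampling makes areas very slightly orientation-dependent — about
half a percent at 960 points — so exact rotational invariance should not
be expected; the tests check invariance at that sampling resolution, and
comparisons against published interface areas should use a generous
(±15%) tolerance since the area method behind any given table is rarely
stated.

## Shared-helix fusion and rotational enumeration

The binder is attached by merging the host's C-terminal helix, an ideal
helical linker of `k` inserted residues, and the binder's N-terminal helix
into one continuous α-helix. Because consecutive helix residues are
related by a fixed twist, stepping `k` rotates the binder about the shared
axis — this is the rotational enumeration used to search for orientations
that pack without collisions.

Ideal helix parameters are `rise = 1.5` Å/residue, `twist = 100`°/residue
(3.6 residues/turn), Cα radius 2.3 Å — standard α-helix values, chosen
here as package defaults because rotational enumeration needs a definite
geometry; all are configurable through `helix_params()`. Backbone N, C, O
are placed at fixed cylindrical offsets from each Cα, and linker side
chains are modelled as alanine (ideal Cβ from the local backbone frame).

`fit_helix_axis()` recovers axis, rise and twist from Cα coordinates via
second differences (which point radially toward the axis of an ideal
helix) followed by a least-squares circle fit in the axis-normal plane.
Fits with radial residual above 0.25 Å, or degenerate geometry (straight
lines), are flagged `nonhelical`; fusion refuses flagged anchors unless
forced.

`shared_helix_fuse()` continues the host anchor by `k` ideal residues
(superposing a canonical ideal helix onto the last 7 anchor Cαs to pick up
position and phase), then rigid-body places the binder by superposing the
first 7 Cαs of its anchor onto the last turn of the extension. The
7-residue window — about two turns — balances phase accuracy against local
curvature and is configurable. The binder's window residues duplicate the
host/extension copy of the shared helix and are dropped, so the fused
model contains the shared helix exactly once; the rest of the binder moves
as a rigid body (its internal distances are preserved to numerical
precision, which the tests assert at 10⁻⁶ Å).

`clash_score()` counts heavy-atom pairs closer than 3.0 Å between the
moving unit (extension + binder) and the host copy plus all symmetry
mates. Residue pairs separated by ≤ 2 positions along the fused chain are
exempt — these are covalent-junction neighbours. A continuous ideal helix
has i→i+4 backbone O⋯N distances just under 3 Å, so a handful of
"clashes" across the junction region is the expected baseline for a
seamless fusion; ranking across `k` values is unaffected because the
baseline is common to all models. `enumerate_rotations()` ranks models by
clash count (ascending), ties by `k`.

`cavity_radius()` reports the largest sphere centred at a chosen point
(typically the binder paratope centroid) that touches no lattice heavy
atom, i.e. the guest diameter the packing can accommodate; an empty
context reports an unbounded cavity.

## Disulfide-crosslink scanning

Extra crystal contacts can be engineered as cysteine bridges, within one
molecule or across symmetry mates. `scan_disulfides()` applies geometric
pre-filters ($d_{C\alpha} \le 7.5$ Å, $d_{C\beta} \in [3, 5]$ Å — a
generous superset of observed disulfide geometry), models Sγ atoms at
1.81 Å/114.6° over a 3 × 3 grid of χ1 rotamers (−60°, 60°, 180°), and
keeps the lowest value of the strain score

$$E = w_1 (d_{C\beta} - 3.85)^2 + w_2 \sum \Delta(\angle
C\alpha C\beta S\gamma, 114.6°)^2 + w_3\, \Delta(\chi_3, \pm 87°)^2,$$

with deviations in Å and radians and unit weights by default. The score is
a transparent geometric ranking device — no claim to physical energies is
made, and candidate *presence*, not rank order, is the robust output.
Glycines get an ideal reconstructed Cβ; residues that are already cysteine
are scanned like any other (their deposited Cβ is used), so engineered
structures validate the scan. Residues with incomplete backbones are
skipped with a warning.

## Rigidity analytics

`kabsch()` computes the least-squares proper rotation by SVD with the
usual reflection correction (det = +1 is enforced; degenerate collinear
inputs error). `pair_atoms()` matches atoms by author chain/residue
number/insertion code/atom name with an optional chain mapping and no
outlier rejection, because published RMSDs for such comparisons are plain
RMSDs over fixed atom sets. `domain_bfactor()` takes unweighted means of
isotropic B over non-hydrogen atoms per residue range; means over a
partition recombine atom-weighted to the global mean. `model_census()`
partitions non-hydrogen atoms into protein (20 standard residues + MSE),
water (HOH/WAT/DOD) and ligand (the rest); the partition sums to the
total by construction.

## Structure I/O conventions

- Author residue numbering is authoritative throughout (published mutation
  and domain identifiers use it).
- Hydrogens are parsed and kept but excluded from every geometric
  computation; censuses are non-hydrogen counts.
- Alternate locations: the default keeps the highest-occupancy conformer
  per residue (ties broken alphabetically); `keep_alt = TRUE` gives the
  raw table. Published atom censuses rarely state their alt-loc
  convention, so counts on multi-conformer models may differ slightly
  from printed values.
- Fixed-column PDB serials above 99999 (and residue numbers above 9999)
  are written in hybrid-36; mmCIF output is lossless and preferred for
  large fused models, which exceed 10,000 atoms.

## The synthetic-data generator

`make_toy_crystal()` places one ideal poly-alanine helix in a user-chosen
cell and space group so that no symmetry copy comes within 2.0 Å of any
other, using a seeded random search over positions and orientations
(deterministic per seed; the packing invariant is verified before
returning, and the crystal system of the cell is validated against the
group). It emulates exactly what the lattice algorithms need — a
self-clash-free chain with a valid symmetric packing — and nothing more:
no side-chain diversity, no solvent, no B-factor structure, no disorder.
Tests passing on these fixtures therefore demonstrate the correctness of
the symmetry, contact, clash and scan machinery, not parser robustness
against messy deposited files or the biological plausibility of any
particular design.

Test problem sizes are kept small by design — cells of 12–50 Å, chains of
3–20 residues, ≤ 1000-atom clash systems — which is the scale at which
the brute-force oracles (all-pairs symmetry enumeration, grid-integrated
SASA, O(n²) clash counting, Euler-grid superposition) remain exact and
cheap.

## Numerical choices and limitations

- Operator translations snap to a 1/12 grid during composition; parsing
  accepts arbitrary fractions/decimals and Unicode minus signs.
- The Shrake–Rupley sampler, the circle fit in the axis fitter and the
  Kabsch SVD are deterministic; the only randomness in the package is the
  seeded placement search of the fixture generator.
- Degenerate inputs error early: non-positive-definite metric tensors,
  empty selections, missing cells for symmetry operations, collinear
  point sets for superposition.
- Out of scope by design: diffraction data handling, refinement, map
  computation, energy-based design and linker sequence optimisation.
  Helix unwinding and other backbone flexibility are not modelled — the
  fusion model is strictly rigid, which is the design assumption the
  workflow is built to test.
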