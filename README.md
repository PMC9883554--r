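# ttfieldsim

Voxel-based simulation of **tumor treating fields (TTFields)** — 200 kHz
alternating electric fields delivered to a glioblastoma through two 3×3
transducer arrays glued to the scalp with hydrogel pads — in synthetic
head phantoms, with and without a **craniectomy (skull defect)** and with
an optional **insulating film** between transducer and gel.

## Who this is for, and what it computes

The skull is the most resistive tissue in the head, so removing a bone
flap opens a low-impedance window that raises the electric field at the
tumor — and the Joule heating of the gel pads, which matters clinically
because the device throttles its voltage at the 41 °C skin limit. This
package lets modelers explore that trade-off quantitatively:

1. **Phantom generator** — nested scalp/skull/CSF/gray/white spherical
   compartments, a two-compartment tumor (low-conductivity enhancing
   shell, high-conductivity necrotic core), a cylindrical skull window
   refilled with scalp tissue, and two opposed 3×3 arrays (gel pads and
   electrode discs conforming to the scalp). Label volumes read/write as
   NIfTI.
2. **Electro-quasistatic solver** — finite-volume discretization of
   `∇·((σ + iωε₀εᵣ)∇φ) = 0` on the voxel grid: 80 V on the active array,
   ground on the other, zero normal current elsewhere, harmonic-mean face
   conductances, and a contact-impedance thin-film condition
   `Y = (σ_f + iωε₀εᵣ_f)/d_f` for insulated transducer–gel interfaces.
   Direct sparse LU for small grids, SSOR-preconditioned
   conjugate-orthogonal CG above.
3. **Dose & thermogenesis metrics** — per-tissue mean/max `|E|` (V/cm),
   above-threshold volume of the tumor shell (ATV at 1.0 and 2.5 V/cm),
   per-gel-pad Joule heating `Q = ½ Re(J·E*)` (W/m³) with the case-level
   maximum `W_max`, and the **power-normalized field strength**

   ```
   E_norm = E₂ · √(W₁ / W₂)
   ```

   which compares cases as if each were throttled to the same maximum pad
   heating (`W₁` = intact-skull benchmark, `W₂` = evaluated case, `E₂` =
   mean tumor-shell field relative to the intact baseline).
4. **Analytic oracles** — layered-slab series closed form and an N-layer
   concentric-sphere Legendre series (polar-cap current injection), used
   as ground truth for the solver's accuracy gates.

## Worked example

Compare the three cases on the shipped superficial-tumor fixture (55 mm
from head center, 12 mm necrotic core, 6 mm shell, 50 mm window under the
active array, 2 mm voxels — about 18 s per case on one CPU):

```r
library(ttfieldsim)

cfg <- study_config(phantom = superficial_fixture_config(spacing = 2))
ct  <- compare_cases(cfg)
print(ct)
#>       case W_max_W_m3 mean_shell_vcm E2_rel E_norm_pct atv_1 atv_2.5
#>     intact    1110000          1.600  1.000      100.0    97     5.0
#>     defect    1330000          2.416  1.510      137.6   100    32.0
#>  insulated    1250000          2.327  1.454      137.0   100    30.9
```

Reading the table: opening the 50 mm window raises the mean tumor-shell
field from 1.60 to 2.42 V/cm (+51 %) and the hottest pad's volumetric
heating from 1.11×10⁶ to 1.33×10⁶ W/m³; the shell volume above the
2.5 V/cm maximal-effect threshold grows from 5 % to 32 %. After
normalizing to equal maximum pad heating the defective case still
delivers 137.6 % of the intact-case dose. Adding the 1 µm insulating film
under the nine defect-side transducers trims the heating peak (−6 %) at a
small cost in field (−3.7 %). On the deep-tumor fixture
(`deep_fixture_config()`) the same window yields only +17 % shell field —
the superficial-versus-deep contrast reported for real head models.

Single pieces are exposed too:

```r
ph  <- build_head_phantom(superficial_fixture_config())
ph  <- embed_tumor(ph, c(55, 0, 0), r_core = 12, t_shell = 6)
ph  <- apply_skull_defect(ph, diameter = 50)
pl  <- place_arrays(ph)
sys <- assemble_system(pl$phantom)
sol <- electric_field(solve_potential(sys))
tissue_field_stats(sol)
atv(sol, threshold = 1.0)
gel_power_stats(joule_heating(sol), pl$phantom)
write_nifti(as_volume(sol, "emag_vcm"), "emag.nii", spacing = 2)
```

And the published worked examples of the normalization statistic:

```r
100 * normalized_field_strength(1.491, 7.26e5, 9.25e5)  # 132.1 (%)
100 * normalized_field_strength(1.107, 6.55e5, 1.02e6)  # 88.7  (%)
```

## Command line

```sh
Rscript -e 'ttfieldsim::ttf_cli()' build   --out out/ --spacing 2
Rscript -e 'ttfieldsim::ttf_cli()' solve   --case defect --out out/
Rscript -e 'ttfieldsim::ttf_cli()' compare --out out/ --deep
Rscript -e 'ttfieldsim::ttf_cli()' oracle  --spacing 2 --out out/
```

`build` writes the label volume as NIfTI (codes: 0 outside, 1 scalp,
2 skull, 3 gray matter, 4 white matter, 5 CSF, 6 tumor shell, 7 tumor
core, 8 hydrogel, 9 electrode, 10 air); `solve` adds `|E|` (V/cm) and `Q`
(W/m³) volumes plus a JSON summary; `compare` emits the three-case table
as CSV/JSON; `oracle` runs the slab and sphere validation fixtures.

## Validation status

The solver is gated against closed forms: homogeneous and two-layer slabs
match the series solution to machine precision, the global power balance
holds to solver tolerance on every fixture (the default Joule-heating map
is energy-conservative by construction), and the 3-layer sphere gate
converges monotonically against the Legendre-series oracle (8.2 / 5.1 /
3.8 / 2.5 % relative L2 at 3 / 2 / 1.5 / 1 mm). Two expectations in
`tests/testthat/test-acceptance.R` are intentionally red: the sphere gate
misses its 5 % bound at 2 mm by 0.14 points (first-order staircase error
of the thin skull shell), and three directional sub-claims about the
idealized spherical head (defect-side pad-max heating, < 5 % brain-mean
change, ATV-gain ordering) do not hold in this geometry for reasons
analyzed in `vignettes/methods.Rmd`.
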