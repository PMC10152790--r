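# Model configuration schema (version 1.0)

A model configuration is a YAML document with the following top-level keys.

```yaml
schema_version: "1.0"     # required
name: <string>            # model label
tree: <node>              # required: the root chance node
cost_table: [<cost row>]  # optional
scenario: <scenario>      # optional
```

## Nodes

A **chance node**:

```yaml
node: <unique id>
dist: fixed | {family: dirichlet, alphas: [a1, a2, ...]}   # optional;
                                                           # omitted = auto
branches:
  - prob: <number in [0,1]>            # or a distribution reference:
    # prob: {family: beta_pert, mode: m, min: lo, max: hi, shape: 4}
    child: <node>
  - ...
```

Constraints: at least 2 branches; numeric branch probabilities must sum
to 1 within 1e-9; node ids unique across the tree. Under the automatic
probabilistic-sensitivity rule, two-branch nodes are redrawn from a
Beta-PERT (mode = estimate, 40% min-max range) and nodes with three or
more branches from a Dirichlet (alphas = estimates x 100); nodes with a
degenerate (0/1) probability or `dist: fixed` are never redrawn.

A **terminal node**:

```yaml
terminal: <unique pathway id>
is_death: true | false
stage: <string>                         # optional stage tag
per_year_costs:                         # exactly 5 entries (years 1..5)
  - {tpp: <num>, oop: <num>, bdl: <num>}   # thousand LBP, >= 0
  - ...
schedule:                               # optional; enables cost redraws
  - {procedure: <id>, counts: [c1, c2, c3, c4, c5]}
  - ...
```

When a terminal carries a `schedule`, every `procedure` must exist in the
cost table supplied to the PSA, and its costs are recomputed per run from
the redrawn cost matrix; terminals without a schedule keep their fixed
`per_year_costs`.

## Cost table rows

```yaml
- procedure_id: <unique id>
  label: <string>
  pre_tpp: <num>    # thousand LBP; pre-collapse BDL is implicitly 0
  pre_oop: <num>
  post_tpp: <num>
  post_oop: <num>
  post_bdl: <num>
```

## Scenario

```yaml
label: pre_collapse | post_collapse | post_collapse_zero_subsidy |
       full_adherence_pre | <custom>
epoch: pre | post
exchange_rate: <LBP per USD>
incidence: <new cases per year>
zero_subsidy: true | false
```

Round-trip guarantee: `read_model_config(write_model_config(m))` returns a
semantically identical model, and a second write produces a byte-identical
file.
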