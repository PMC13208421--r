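version: 1
species:
  - pulverulentus
  - mediterraneensis
  - poikilochromus
microscopy_key:
  scope: mature basidiospores in side view only
  thresholds:
    width_split_um: 5.0
    length_upper_um: 12.5
    length_lower_um: 12.0
    depression_pronounced_pct: 3.0
    depression_shallow_pct: 2.5
  couplets:
    - id: 1
      character: average basidiospore width (um)
      branches:
        - {branch: a, test: "width < 5", goto: 2}
        - {branch: b, test: "width > 5", goto: 4}
    - id: 2
      character: average basidiospore length (um)
      branches:
        - {branch: a, test: "length > 12.5", species: pulverulentus}
        - {branch: b, test: "length < 12.5", goto: 3}
    - id: 3
      character: spore shape, suprahilar depression, gloeocystidia
      branches:
        - {branch: a, test: "mostly ellipsoid, poorly defined depression,
            blunt apex; gloeocystidia abundant", species: poikilochromus}
        - {branch: b, test: "often narrowly amygdaliform, pronounced
            lateralised apiculus and depression, relatively acute apex;
            gloeocystidia sparse", species: pulverulentus}
    - id: 4
      character: average length, spore shape, gloeocystidia
      branches:
        - {branch: a, test: "length < 12.5, mostly ellipsoidal;
            gloeocystidia abundant", species: poikilochromus}
        - {branch: b, test: "length > 12.0, often narrowly subamygdaliform
            or amygdaliform with more or less evident depression;
            gloeocystidia sparse", goto: 5}
    - id: 5
      character: suprahilar depression as percentage of convex hull area
      branches:
        - {branch: a, test: "depression generally > 3% of hull area",
           species: pulverulentus}
        - {branch: b, test: "depression generally < 2.5% of hull area",
           species: mediterraneensis}
macromorphology_key:
  status: experimental, data-only; not evaluated by the package
  couplets:
    - id: 1
      branches:
        - {branch: a, test: "stipe with well-defined reticulum; rounded
            pores; fermented-fruit smell; calcareous Mediterranean soils",
           species: poikilochromus}
        - {branch: b, test: "stipe without reticulum; angular pores;
            indistinct smell", goto: 2}
    - id: 2
      branches:
        - {branch: a, test: "pileus slightly viscous or silky; margin acute;
            context turns dark blue with greenish shades; temperate Europe",
           species: pulverulentus}
        - {branch: b, test: "pileus persistently felty; margin involute or
            obtuse; context turns deep ink blue; Mediterranean thermophilic
            habitats", goto: 3}
    - id: 3
      branches:
        - {branch: a, test: "pileus snuff to buff brown; stipe often brick
            red at base", species: mediterraneensis f. mediterraneensis}
        - {branch: b, test: "pileus light buff to pale yellow; stipe light
            yellow", species: mediterraneensis f. pallidus}
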