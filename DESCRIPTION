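Package: laiscape
Title: Wall-to-Wall Leaf Area Index Mapping from Spaceborne LiDAR
    Footprints, Geostatistical Simulation and Optimized Machine Learning
Version: 0.1.0
Authors@R:
    person("laiscape", "developers", email = "laiscape@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating forest (bamboo) leaf area index (LAI)
    over large areas by fusing sparse spaceborne-LiDAR footprint
    attributes with optical and SAR imagery.  Provides a synthetic-scene
    generator with known ground truth; simplified photon denoising and
    progressive-TIN ground/canopy classification; variogram analysis,
    simple kriging and sequential Gaussian conditional simulation to turn
    footprint point data into wall-to-wall surfaces; GLCM texture and
    vegetation-index feature extraction; Pearson significance screening;
    random forest, gradient-boosted-tree and support-vector regressors
    tuned by Bayesian optimization, particle swarm, genetic algorithm and
    simulated annealing; and leave-one-out cross-validated model
    comparison, LAI mapping and contribution-rate reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
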