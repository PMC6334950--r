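Package: bovacid
Title: Blood and Urine Acid-Base Profiling of Transition Dairy Cows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes traditional (Henderson-Hasselbalch bicarbonate, Van
    Slyke base excess, anion gap) and strong-ion (measured strong ion
    difference, acid total, strong ion gap, unmeasured anions) acid-base
    variables from venous blood panels of dairy cattle, together with
    urinary net acid-base excretion and base-acid ratio from titration
    components.  Derives internal reference intervals from a designated
    reference group, classifies animals qualitatively against internal and
    literature bounds, and groups cows into physiological states by
    standardized Euclidean/Ward hierarchical clustering with
    silhouette-guided selection of the cluster number.  Includes a
    physiologically coupled synthetic-cohort generator emulating a
    seven-cluster post-parturient herd so the full pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
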