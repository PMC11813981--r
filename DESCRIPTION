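Package: thalparc
Title: Winner-Take-All Thalamic Parcellation and Thalamocortical
    Connectivity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("thalparc", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Connectivity-based parcellation of the thalamus from
    resting-state BOLD data and group comparison of thalamocortical
    functional connectivity in stroke cohorts. Implements a minimal NIfTI-1
    volume layer, the standard resting-state denoising chain (initial-volume
    discard, motion QC, linear detrending, 0.01-0.08 Hz band-pass, nuisance
    regression), mid-sagittal lesion-side harmonization with flip-augmented
    controls, winner-take-all parcellation of each thalamus against six
    cortical regions, ROI-to-ROI and seed-to-voxel connectivity on the
    Fisher-z scale, permutation cluster-level familywise-error inference,
    behavioral correlation with Fugl-Meyer motor scores, and a fully
    deterministic synthetic-cohort generator with stored ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
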