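# Shared fixtures: the published regional frequency tallies and a template
# measurement record for classification tests.

fc_east <- clovis_freq_counts()$East
fc_west <- clovis_freq_counts()$West

template_record <- function(...) {
  rec <- list(specimen_id = "s1", assemblage_id = "a1", region = "East",
              max_width_half = "proximal", ear_span_a = 30,
              basal_depth_b = 3, medial_length = 55, maximum_length = 60,
              min_blade_width_proximal = 20, maximum_blade_width = 22,
              left_tang_angle = 90, right_tang_angle = 91,
              left_ear_pointed = TRUE, right_ear_pointed = TRUE)
  utils::modifyList(rec, list(...))
}

# build a classified table from per-assemblage class sets
classified_from_sets <- function(sets, regions) {
  do.call(rbind, lapply(names(sets), function(a) {
    data.frame(specimen_id = paste0(a, "_", seq_along(sets[[a]])),
               assemblage_id = a, region = regions[[a]],
               class_code = sets[[a]], stringsAsFactors = FALSE)
  }))
}
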