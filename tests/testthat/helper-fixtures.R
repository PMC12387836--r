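# fixtures built in code: tiny volumes, label maps and an independent
# per-voxel brute-force volumetrics oracle

two_segment_table <- function() {
  data.frame(code = c(1L, 2L),
             laterality = c("right", "right"),
             lobe = c("RUL", "RLL"),
             segment = c("S1", "S6"),
             stringsAsFactors = FALSE)
}

# uniform HU volume fully covered by one segment
uniform_fixture <- function(hu = -750, dims = c(10, 10, 10), spacing = c(1, 1, 1)) {
  vol <- hu_volume(array(hu, dim = dims), spacing = spacing)
  tab <- data.frame(code = 1L, laterality = "right", lobe = "RUL",
                    segment = "S1", stringsAsFactors = FALSE)
  list(vol = vol, labels = lung_label_map(array(1L, dim = dims), tab))
}

# independent oracle: per-voxel loop, no vectorised tallying
brute_force_volumetrics <- function(vol, labels, theta_emph = -900,
                                    theta_well_max = -501) {
  vml <- prod(vol$spacing) / 1000
  codes <- sort(unique(as.vector(labels$labels)))
  codes <- codes[codes > 0]
  out <- list()
  for (cd in codes) {
    n_well <- 0; n_emph <- 0; n_non <- 0
    for (i in seq_along(labels$labels)) {
      if (labels$labels[i] == cd) {
        h <- vol$values[i]
        if (h < theta_emph) n_emph <- n_emph + 1
        else if (h > theta_well_max) n_non <- n_non + 1
        else n_well <- n_well + 1
      }
    }
    out[[as.character(cd)]] <- c(total = (n_well + n_emph + n_non) * vml,
                                 well = n_well * vml, emph = n_emph * vml,
                                 non = n_non * vml)
  }
  out
}

# hand-constructed per-segment volumetrics rows for simulate_resection tests
manual_volumetrics <- function(region_id, laterality, total, well,
                               emph = 0, non = NULL) {
  if (is.null(non)) non <- total - well - emph
  data.frame(region_id = as.character(region_id), level = "segment",
             laterality = laterality, lobe = NA, segment = NA,
             volume_total_ml = total, volume_well_aerated_ml = well,
             volume_emphysematous_ml = emph, volume_non_aerated_ml = non,
             stringsAsFactors = FALSE)
}
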