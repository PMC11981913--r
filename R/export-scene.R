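# Scene export: mesh files plus a JSON ground-truth sidecar and synapse CSV.

#' Export a merge scene to disk
#'
#' Writes the scene mesh (OFF or binary PLY), the per-face ground-truth
#' labels and error records as a JSON sidecar, and the synapse table as CSV
#' with a `valid` 0/1 column.
#'
#' @param scene a `merge_scene`.
#' @param dir output directory (created if needed).
#' @param format `"off"` (default) or `"ply"`.
#' @return the directory, invisibly.
#' @export
export_scene <- function(scene, dir, format = c("off", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "off") write_off(scene$mesh, file.path(dir, "scene.off"))
  else write_ply(scene$mesh, file.path(dir, "scene.ply"))
  sidecar <- list(
    face_labels = scene$labels,
    error_truth = lapply(seq_len(nrow(scene$error_truth)), function(i)
      list(error_id = scene$error_truth$error_id[i],
           type = scene$error_truth$type[i],
           weld = c(scene$error_truth$weld_x[i],
                    scene$error_truth$weld_y[i],
                    scene$error_truth$weld_z[i]),
           face_ids = scene$error_truth$face_ids[[i]])),
    n_neurons = length(scene$neurons))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(scene$synapses) && nrow(scene$synapses) > 0)
    write_synapse_csv(scene$synapses, file.path(dir, "synapses.csv"))
  invisible(dir)
}
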