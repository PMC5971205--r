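#' Packaged generator presets
#'
#' The synthetic-data generator encodes the study conditions it emulates as
#' named presets in a single configuration file
#' (`inst/extdata/presets.yaml`): FRAP ground truths per assembly class
#' (e.g. `mammalian-dim`, `yeast-bright`), the two-assembly exchange
#' condition, the dim/bright morphometric populations on the (IR, CR) plane,
#' the droplet ring-offset condition, and the default dot-blot layout.
#'
#' @param group preset group: `"frap"`, `"exchange"`, `"morphology"`,
#'   `"radial_shift"` or `"blot"`. `NULL` returns the full preset tree.
#' @param name preset name within the group; `NULL` returns the whole group.
#' @return a named list of preset parameters.
#' @export
#' @examples
#' condensate_preset("frap", "mammalian-dim")$mobile_fraction
condensate_preset <- function(group = NULL, name = NULL) {
  path <- system.file("extdata", "presets.yaml", package = "condensatetools")
  presets <- yaml::read_yaml(path)
  if (is.null(group)) return(presets)
  if (!group %in% names(presets))
    stop(sprintf("unknown preset group '%s'", group))
  g <- presets[[group]]
  if (is.null(name)) return(g)
  if (!name %in% names(g))
    stop(sprintf("unknown preset '%s' in group '%s' (have: %s)",
                 name, group, paste(names(g), collapse = ", ")))
  g[[name]]
}
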