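#' Local identifier registry
#'
#' Each site keeps a local registry of issued identifiers so the
#' duplication check can run before an identifier enters use; there is no
#' central codebook. Entries map identifier strings to an opaque local
#' reference. Backed by an environment, so inserts mutate in place.
#'
#' @param site Label of the issuing site.
#' @param profile The [nhash_profile()] all entries must conform to.
#' @return An object of class `nhash_registry`.
#' @export
nhash_registry <- function(site = "local", profile = csr_profile()) {
  structure(
    list(entries = new.env(parent = emptyenv(), hash = TRUE),
         site = site, profile = profile),
    class = "nhash_registry"
  )
}

#' @rdname nhash_registry
#' @param registry An `nhash_registry`.
#' @param id Identifier string.
#' @export
registry_contains <- function(registry, id) {
  exists(id, envir = registry$entries, inherits = FALSE)
}

#' @rdname nhash_registry
#' @param ref Opaque local reference stored with the entry.
#' @param created Timestamp string; defaults to now (UTC).
#' @export
registry_add <- function(registry, id, ref = NA_character_, created = NULL) {
  if (registry_contains(registry, id))
    stop(nhash_error("duplicate_id",
      sprintf("identifier %s already present in registry", id)))
  if (is.null(created))
    created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  assign(id, list(ref = ref, site = registry$site, created = created),
         envir = registry$entries)
  invisible(registry)
}

#' @rdname nhash_registry
#' @export
registry_ids <- function(registry) {
  sort(ls(envir = registry$entries))
}

#' @rdname nhash_registry
#' @export
registry_size <- function(registry) {
  length(ls(envir = registry$entries))
}

#' @export
print.nhash_registry <- function(x, ...) {
  cat(sprintf("NHash registry (site %s, profile %s): %d entries\n",
              x$site, profile_tag(x$profile), registry_size(x)))
  invisible(x)
}

#' Persist and reload a registry as JSON lines
#'
#' One JSON object per line with fields `id`, `ref`, `site`, `created` —
#' an append-friendly audit format. `registry_load()` round-trips a saved
#' file byte-for-byte at the entry level.
#'
#' @param registry An [nhash_registry()].
#' @param path File path.
#' @export
registry_save <- function(registry, path) {
  ids <- registry_ids(registry)
  lines <- vapply(ids, function(id) {
    e <- get(id, envir = registry$entries)
    jsonlite::toJSON(list(id = id, ref = e$ref, site = e$site,
                          created = e$created),
                     auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname registry_save
#' @param site,profile Metadata for the reloaded registry object.
#' @export
registry_load <- function(path, site = "local", profile = csr_profile()) {
  reg <- nhash_registry(site = site, profile = profile)
  lines <- readLines(path, warn = FALSE)
  for (line in lines[nzchar(lines)]) {
    e <- jsonlite::fromJSON(line)
    registry_add(reg, e$id,
                 ref = if (is.null(e$ref)) NA_character_ else e$ref,
                 created = e$created)
    entry <- get(e$id, envir = reg$entries)
    entry$site <- if (is.null(e$site)) NA_character_ else e$site
    assign(e$id, entry, envir = reg$entries)
  }
  reg
}

#' Merge an incoming site registry into a central one
#'
#' Returns the union of both registries plus the list of identifiers
#' present in both — cross-site collisions, which the issuing site must
#' resolve by regenerating. Nothing is silently overwritten: for colliding
#' identifiers the merged registry keeps the central entry and the
#' collision list carries both references.
#'
#' @param central,incoming Two [nhash_registry()] objects using the same
#'   profile.
#' @return A list with `merged` (a new registry) and `collisions` (a
#'   data.frame with columns `id`, `central_ref`, `incoming_ref`,
#'   `central_site`, `incoming_site`).
#' @export
merge_registries <- function(central, incoming) {
  if (profile_tag(central$profile) != profile_tag(incoming$profile))
    stop(nhash_error("profile_mismatch",
      "registries were built under different hash profiles"))
  merged <- nhash_registry(site = central$site, profile = central$profile)
  for (id in registry_ids(central)) {
    e <- get(id, envir = central$entries)
    registry_add(merged, id, ref = e$ref, created = e$created)
    entry <- get(id, envir = merged$entries); entry$site <- e$site
    assign(id, entry, envir = merged$entries)
  }
  coll <- list()
  for (id in registry_ids(incoming)) {
    e <- get(id, envir = incoming$entries)
    if (registry_contains(merged, id)) {
      ce <- get(id, envir = merged$entries)
      coll[[length(coll) + 1L]] <- data.frame(
        id = id, central_ref = ce$ref, incoming_ref = e$ref,
        central_site = ce$site, incoming_site = e$site,
        stringsAsFactors = FALSE)
    } else {
      registry_add(merged, id, ref = e$ref, created = e$created)
      entry <- get(id, envir = merged$entries); entry$site <- e$site
      assign(id, entry, envir = merged$entries)
    }
  }
  collisions <- if (length(coll)) do.call(rbind, coll) else
    data.frame(id = character(), central_ref = character(),
               incoming_ref = character(), central_site = character(),
               incoming_site = character(), stringsAsFactors = FALSE)
  list(merged = merged, collisions = collisions)
}
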