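#' File-backed document store
#'
#' An embedded, schema-free document store reproducing the server's
#' collection scheme: named collections of JSON documents with unique
#' `_id` fields, persisted one collection per JSONL file under a root
#' directory. Three fixed collections hold actors and task
#' configuration (`User`, `Task`, `Task_Parameters`); each
#' rehabilitation session is stored in its own
#' `Session_<unique_identifier>` collection so the collection name alone
#' carries all retrieval information. Writes are atomic per call
#' (temp-file rename).
#'
#' @param root Store root directory.
#' @return `store_init` creates the layout and returns a `session_store_db`
#'   handle; `store_open` opens an existing root.
#' @export
store_init <- function(root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(root, "staging"), showWarnings = FALSE)
  for (coll in c("User", "Task", "Task_Parameters"))
    if (!file.exists(.coll_path(root, coll)))
      writeLines(character(), .coll_path(root, coll))
  store_open(root)
}

#' @rdname store_init
#' @export
store_open <- function(root) {
  if (!dir.exists(root)) stop("store root does not exist: ", root)
  structure(list(root = root), class = "session_store_db")
}

.coll_path <- function(root, name) file.path(root, paste0(name, ".jsonl"))

#' List the collections of a store
#'
#' @param store A `session_store_db` handle.
#' @return Character vector of collection names.
#' @export
store_collections <- function(store) {
  sub("\\.jsonl$", "", list.files(store$root, pattern = "\\.jsonl$"))
}

.read_coll <- function(store, name) {
  p <- .coll_path(store$root, name)
  if (!file.exists(p)) return(list())
  lines <- readLines(p, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = FALSE)
}

.write_coll <- function(store, name, docs) {
  p <- .coll_path(store$root, name)
  tmp <- paste0(p, ".tmp")
  writeLines(vapply(docs, function(d) as.character(.tojson(d)), ""),
             tmp, useBytes = TRUE)
  file.rename(tmp, p)
  invisible(p)
}

## --- roles ------------------------------------------------------------

# total role matrix: every (role, collection kind, op) triple is defined.
# Therapists manage patients, tasks, parameters and session data; session
# streams are immutable once inserted (no update; deletion of old records
# is an administrator operation). Patients only read their assigned task
# material and insert session data through the rehabilitation system.
.ROLES <- c("patient", "therapist", "administrator")
.OPS <- c("create", "read", "update", "delete")
.KINDS <- c("User", "Task", "Task_Parameters", "Session")

.role_matrix <- function() {
  g <- expand.grid(role = .ROLES, collection = .KINDS, op = .OPS,
                   stringsAsFactors = FALSE)
  allowed <- function(r, k, o) {
    if (r == "administrator")       # full CRUD on fixed collections;
      return(k != "Session" ||      # sessions immutable, but old records
               o %in% c("read", "delete"))   # may be deleted
    if (r == "therapist")
      return(k != "Session" || o %in% c("create", "read"))
    # patient: read assigned task material, insert/read session data
    (k %in% c("Task", "Task_Parameters") && o == "read") ||
      (k == "Session" && o %in% c("create", "read"))
  }
  g$allow <- mapply(allowed, g$role, g$collection, g$op)
  g
}

.ROLE_MATRIX <- .role_matrix()

#' Role-permission lookup
#'
#' The access-control matrix is total: every (role, collection-kind,
#' operation) triple has a defined allow/deny. Therapists hold full CRUD
#' over patients, tasks and task parameters and may insert and read
#' session data; administrators additionally manage therapists,
#' credentials and patient-therapist links and may delete old session
#' collections; patients may read their task material and insert/read
#' session data. Session collections are immutable once written: nobody
#' may update them.
#'
#' @param role `"patient"`, `"therapist"` or `"administrator"`.
#' @param collection Collection name; `Session_*` names map to the
#'   `Session` kind.
#' @param op `"create"`, `"read"`, `"update"` or `"delete"`.
#' @return Logical scalar.
#' @export
role_allows <- function(role, collection, op) {
  kind <- if (startsWith(collection, "Session")) "Session" else collection
  if (!role %in% .ROLES) stop("unknown role: ", role)
  if (!kind %in% .KINDS) stop("unknown collection: ", collection)
  if (!op %in% .OPS) stop("unknown op: ", op)
  m <- .ROLE_MATRIX
  m$allow[m$role == role & m$collection == kind & m$op == op]
}

#' Role-checked CRUD on a store collection
#'
#' Performs one create/read/update/delete call against a collection
#' after checking the caller's role (see [role_allows()]). Creates
#' enforce `_id` uniqueness; updates and deletes require an existing
#' `_id`; `Task_Parameters` documents must reference an existing task.
#'
#' @param store A `session_store_db` handle.
#' @param role Caller role (the caller-supplied identity; real
#'   authentication is out of scope).
#' @param collection Collection name.
#' @param op One of `"create"`, `"read"`, `"update"`, `"delete"`.
#' @param doc Document (named list with `_id`) for create/update/delete;
#'   for `read`, an optional filter list matched by equality on its
#'   fields (`NULL` reads all).
#' @return For `read`, the list of matching documents; otherwise the
#'   affected document, invisibly.
#' @export
store_crud <- function(store, role, collection, op, doc = NULL) {
  if (!isTRUE(role_allows(role, collection, op)))
    stop(sprintf("authorization error: role '%s' may not %s on '%s'",
                 role, op, collection))
  docs <- .read_coll(store, collection)
  ids <- vapply(docs, function(d) as.character(d$`_id` %||% ""), "")
  if (op == "read") {
    if (is.null(doc)) return(docs)
    keep <- vapply(docs, function(d)
      all(vapply(names(doc), function(f)
        identical(d[[f]], doc[[f]]), logical(1))), logical(1))
    return(docs[keep])
  }
  if (is.null(doc$`_id`)) stop("document must carry an _id")
  if (collection == "Task_Parameters" && op %in% c("create", "update")) {
    tasks <- .read_coll(store, "Task")
    task_ids <- vapply(tasks, function(d) as.character(d$`_id`), "")
    if (is.null(doc$task_id) || !doc$task_id %in% task_ids)
      stop("integrity error: Task_Parameters must reference an existing Task")
  }
  i <- match(doc$`_id`, ids)
  if (op == "create") {
    if (!is.na(i)) stop("integrity error: duplicate _id ", doc$`_id`,
                        " in ", collection)
    docs[[length(docs) + 1L]] <- doc
  } else if (op == "update") {
    if (is.na(i)) stop("integrity error: no document ", doc$`_id`)
    docs[[i]] <- utils::modifyList(docs[[i]], doc)
  } else {                                          # delete
    if (is.na(i)) stop("integrity error: no document ", doc$`_id`)
    docs[[i]] <- NULL
  }
  .write_coll(store, collection, docs)
  invisible(doc)
}

## --- session identifiers & session collections ------------------------

.sanitize_id_component <- function(x) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop("identifier components must be non-empty strings")
  gsub("[^A-Za-z0-9.-]", "-", x)
}

#' Build the unique session identifier
#'
#' The identifier is a deterministic, filesystem-safe join of the
#' patient id, therapist id, task-parameters id and session date:
#' `Session_<userp>_<usert>_<params>_<YYYYMMDD>`. Components are
#' sanitized (characters outside `[A-Za-z0-9.-]`, including the
#' underscore separator itself, become `-`), so the join is injective
#' over sanitized inputs and the collection name parses back into its
#' components.
#'
#' @param id_userp Patient id.
#' @param id_usert Therapist id.
#' @param id_task_parameters Task-parameters id.
#' @param date Session date (`Date` or `"YYYY-MM-DD"` string).
#' @return The identifier string.
#' @export
make_session_identifier <- function(id_userp, id_usert,
                                    id_task_parameters, date) {
  d <- format(as.Date(date), "%Y%m%d")
  paste("Session",
        .sanitize_id_component(id_userp),
        .sanitize_id_component(id_usert),
        .sanitize_id_component(id_task_parameters),
        d, sep = "_")
}

#' @rdname make_session_identifier
#' @param identifier A string produced by [make_session_identifier()].
#' @return `parse_session_identifier` returns a list with `id_userp`,
#'   `id_usert`, `id_task_parameters` and `date`.
#' @export
parse_session_identifier <- function(identifier) {
  parts <- strsplit(identifier, "_", fixed = TRUE)[[1]]
  if (length(parts) != 5L || parts[1] != "Session")
    stop("not a session identifier: ", identifier)
  list(id_userp = parts[2], id_usert = parts[3],
       id_task_parameters = parts[4],
       date = as.Date(parts[5], format = "%Y%m%d"))
}

#' Insert a session stream into the store
#'
#' Stores a completed session under its own
#' `Session_<unique_identifier>` collection. The identifier components
#' must resolve to existing users and task parameters (integrity
#' errors otherwise). The stream is first written to a local staging
#' area and only then transferred into the store -- emulating the
#' support-instance buffering that protects against connection loss;
#' the staging copy is cleared once the transfer is confirmed, and a
#' retry after a simulated transfer failure completes idempotently
#' (exactly one stored copy).
#'
#' @param store A `session_store_db` handle.
#' @param stream A [session_stream()] whose header carries `patient_id`,
#'   `therapist_id` and `task$params_id`.
#' @param role Caller role, default `"patient"` (the rehabilitation
#'   system inserts on the patient's behalf).
#' @param fail_transfer Fault injection: when `TRUE` the function stops
#'   after staging, before the transfer.
#' @return The session collection name, invisibly.
#' @export
insert_session <- function(store, stream, role = "patient",
                           fail_transfer = FALSE) {
  stopifnot(inherits(stream, "session_stream"))
  h <- stream$header
  params_id <- h$task$params_id %||% stop("header task lacks params_id")
  if (!isTRUE(role_allows(role, "Session", "create")))
    stop("authorization error: role '", role, "' may not insert sessions")
  users <- .read_coll(store, "User")
  uid <- vapply(users, function(d) as.character(d$`_id`), "")
  if (!h$patient_id %in% uid)
    stop("integrity error: unknown patient id ", h$patient_id)
  if (!h$therapist_id %in% uid)
    stop("integrity error: unknown therapist id ", h$therapist_id)
  pid <- vapply(.read_coll(store, "Task_Parameters"),
                function(d) as.character(d$`_id`), "")
  if (!params_id %in% pid)
    stop("integrity error: unknown task parameters id ", params_id)

  name <- make_session_identifier(h$patient_id, h$therapist_id, params_id,
                                  h$task$start_date)
  staged <- file.path(store$root, "staging", paste0(name, ".vgs.jsonl"))
  stored <- .coll_path(store$root, name)
  if (file.exists(stored) && !file.exists(staged))
    stop("integrity error: session collection already exists: ", name)
  if (!file.exists(staged)) write_stream(stream, staged)
  if (fail_transfer) stop("transfer failure (simulated); staged copy retained")
  file.copy(staged, stored, overwrite = TRUE)
  unlink(staged)
  invisible(name)
}

#' Read a stored session stream back
#'
#' @param store A `session_store_db` handle.
#' @param name Session collection name.
#' @param role Caller role, default `"therapist"`.
#' @return The [session_stream()]; the stored data remain intact.
#' @export
read_session <- function(store, name, role = "therapist") {
  if (!isTRUE(role_allows(role, "Session", "read")))
    stop("authorization error: role '", role, "' may not read sessions")
  p <- .coll_path(store$root, name)
  if (!file.exists(p)) stop("no such session collection: ", name)
  read_stream(p)
}

#' Query stored sessions by therapist criteria
#'
#' Finds session collections matching all supplied criteria: patient id
#' or patient name (resolved through the `User` collection), task type
#' (resolved through `Task_Parameters` and `Task`), and an execution
#' date range parsed from the collection identifier.
#'
#' @param store A `session_store_db` handle.
#' @param patient_id,patient_name,task_type Optional equality criteria.
#' @param from,to Optional date-range bounds (inclusive).
#' @param role Caller role, default `"therapist"`.
#' @return Character vector of matching session collection names (empty
#'   when none match).
#' @export
query_sessions <- function(store, patient_id = NULL, patient_name = NULL,
                           task_type = NULL, from = NULL, to = NULL,
                           role = "therapist") {
  if (!isTRUE(role_allows(role, "Session", "read")))
    stop("authorization error: role '", role, "' may not query sessions")
  names <- grep("^Session_", store_collections(store), value = TRUE)
  if (!is.null(patient_name)) {
    users <- .read_coll(store, "User")
    ids <- vapply(users[vapply(users, function(d)
      identical(d$name, patient_name), logical(1))],
      function(d) as.character(d$`_id`), "")
    if (is.null(patient_id)) patient_id <- ids
    else patient_id <- intersect(patient_id, ids)
    if (!length(patient_id)) return(character())
  }
  keep <- vapply(names, function(nm) {
    info <- tryCatch(parse_session_identifier(nm), error = function(e) NULL)
    if (is.null(info)) return(FALSE)
    if (!is.null(patient_id) && !info$id_userp %in% patient_id) return(FALSE)
    if (!is.null(task_type)) {
      params <- .read_coll(store, "Task_Parameters")
      p <- Filter(function(d) identical(as.character(d$`_id`),
                                        info$id_task_parameters), params)
      if (!length(p)) return(FALSE)
      tasks <- .read_coll(store, "Task")
      tk <- Filter(function(d) identical(as.character(d$`_id`),
                                         as.character(p[[1]]$task_id)), tasks)
      if (!length(tk) || !identical(tk[[1]]$name, task_type)) return(FALSE)
    }
    if (!is.null(from) && info$date < as.Date(from)) return(FALSE)
    if (!is.null(to) && info$date > as.Date(to)) return(FALSE)
    TRUE
  }, logical(1))
  unname(names[keep])
}
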