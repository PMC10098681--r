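# store fixtures, built in code at test time

# populate a store with users/tasks/params; returns the handle
seed_store <- function(root) {
  st <- store_init(root)
  store_crud(st, "therapist", "User", "create",
             list(`_id` = "p1", role = "patient", name = "Ada",
                  therapist_id = "t1", device_id = "vg1"))
  store_crud(st, "therapist", "User", "create",
             list(`_id` = "p2", role = "patient", name = "Grace",
                  therapist_id = "t1", device_id = "vg2"))
  store_crud(st, "administrator", "User", "create",
             list(`_id` = "t1", role = "therapist", name = "Tess"))
  store_crud(st, "administrator", "User", "create",
             list(`_id` = "t2", role = "therapist", name = "Tom"))
  store_crud(st, "therapist", "Task", "create",
             list(`_id` = "keyboard", name = "keyboard",
                  description = "light up buttons"))
  store_crud(st, "therapist", "Task", "create",
             list(`_id` = "grasp", name = "grasp", description = "grasping"))
  store_crud(st, "therapist", "Task_Parameters", "create",
             list(`_id` = "tp1", task_id = "keyboard", duration = 30,
                  difficulty = 1, repetitions = 2,
                  starting_date = "2023-03-25"))
  store_crud(st, "therapist", "Task_Parameters", "create",
             list(`_id` = "tp2", task_id = "grasp", duration = 60,
                  difficulty = 2, repetitions = 1,
                  starting_date = "2023-04-01"))
  st
}

session_for <- function(patient, therapist, params, date, n = 3) {
  task <- list(type = "simulated", difficulty = 1, duration = 30,
               repetitions = 1, start_date = date, params_id = params)
  hdr <- session_header(patient, therapist, "vg1", task = task)
  recs <- lapply(seq_len(n), function(i) {
    f <- make_frame((i - 1) * 25, source = "fused")
    frame_record((i - 1) * 25, list(fused = f))
  })
  session_stream(hdr, recs)
}
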