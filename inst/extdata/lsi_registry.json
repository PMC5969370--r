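{
  "_comment": [
    "Default life-saving-intervention (LSI) vocabulary: receipt of any one of",
    "these interventions defines a true Priority One casualty. The items are a",
    "synthetic reconstruction of the consensus-derived LSI list used in the",
    "major-incident triage literature (the source figure reproduces that",
    "consensus list); item wording here is editorial, not verbatim. This file",
    "is the single source of truth for ground-truth labelling: edit or replace",
    "it to match your registry's intervention coding. Matching is by exact code."
  ],
  "interventions": [
    {"code": "intubation", "label": "Endotracheal intubation for actual or impending airway compromise"},
    {"code": "surgical_airway", "label": "Surgical airway (cricothyroidotomy or emergency tracheostomy)"},
    {"code": "needle_thoracocentesis", "label": "Needle thoracocentesis for tension pneumothorax"},
    {"code": "chest_drain", "label": "Tube thoracostomy (chest drain insertion)"},
    {"code": "chest_seal", "label": "Occlusive chest seal for open chest wound"},
    {"code": "assisted_ventilation", "label": "Positive-pressure or assisted ventilation"},
    {"code": "tourniquet", "label": "Tourniquet application for catastrophic limb haemorrhage"},
    {"code": "haemostatic_dressing", "label": "Haemostatic dressing with direct pressure for catastrophic haemorrhage"},
    {"code": "massive_transfusion", "label": "Transfusion of four or more units of blood products"},
    {"code": "surgical_haemorrhage_control", "label": "Operative control of haemorrhage (laparotomy or thoracotomy)"},
    {"code": "resuscitative_thoracotomy", "label": "Resuscitative (emergency department) thoracotomy"},
    {"code": "pelvic_binder", "label": "Pelvic binder or external pelvic fixation for unstable pelvic injury"},
    {"code": "pericardiocentesis", "label": "Pericardiocentesis for cardiac tamponade"},
    {"code": "acls", "label": "Receipt of ACLS (advanced cardiovascular life support) including defibrillation"},
    {"code": "vasopressors", "label": "Vasopressor or inotrope infusion for shock"},
    {"code": "fluid_resuscitation_shock", "label": "Volume resuscitation for decompensated shock"},
    {"code": "emergency_amputation", "label": "Emergency (field or immediate) amputation"},
    {"code": "fasciotomy", "label": "Fasciotomy for limb compartment syndrome"},
    {"code": "escharotomy", "label": "Escharotomy for circumferential burns"},
    {"code": "craniotomy", "label": "Emergency craniotomy or burr-hole decompression"},
    {"code": "osmotherapy", "label": "Osmotherapy for raised intracranial pressure"},
    {"code": "seizure_control", "label": "Emergency pharmacological seizure termination"},
    {"code": "antidote", "label": "Antidote administration for toxic exposure"},
    {"code": "active_rewarming", "label": "Active core rewarming for severe hypothermia"}
  ]
}
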