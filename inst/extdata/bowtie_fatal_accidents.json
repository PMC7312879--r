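{
  "top_event": "Fatal accident in a metallurgical enterprise",
  "causes": [
    {
      "id": "c1",
      "label": "Insufficient safety training"
    },
    {
      "id": "c2",
      "label": "Lack of inspection in fieldwork"
    },
    {
      "id": "c3",
      "label": "Incomplete safe operation guidelines"
    },
    {
      "id": "c4",
      "label": "Lack of accident prevention measures"
    }
  ],
  "consequences": [
    {
      "id": "q1",
      "label": "Casualties"
    },
    {
      "id": "q2",
      "label": "Equipment trouble"
    },
    {
      "id": "q3",
      "label": "Environmental pollution"
    }
  ],
  "preventive_barriers": [
    {
      "id": "pb1",
      "label": "Regular safety training and assessment of employees",
      "target": "c1"
    },
    {
      "id": "pb2",
      "label": "Routine field inspection and hazard patrols",
      "target": "c2"
    },
    {
      "id": "pb3",
      "label": "Complete and enforced safe operation guidelines",
      "target": "c3"
    },
    {
      "id": "pb4",
      "label": "Accident prevention measures for each production step",
      "target": "c4"
    }
  ],
  "mitigative_barriers": [
    {
      "id": "mb1",
      "label": "Emergency response plan and command organization",
      "target": "q1"
    },
    {
      "id": "mb2",
      "label": "First aid and on-site medical rescue",
      "target": "q1"
    },
    {
      "id": "mb3",
      "label": "Gas detection and alarm systems",
      "target": "q1"
    },
    {
      "id": "mb4",
      "label": "Emergency ventilation of confined spaces",
      "target": "q1"
    },
    {
      "id": "mb5",
      "label": "Fire-fighting equipment and systems",
      "target": "q2"
    },
    {
      "id": "mb6",
      "label": "Evacuation routes and regular drills",
      "target": "q1"
    },
    {
      "id": "mb7",
      "label": "Personal protective equipment for rescuers",
      "target": "q1"
    },
    {
      "id": "mb8",
      "label": "Emergency shutdown of equipment and energy isolation",
      "target": "q2"
    },
    {
      "id": "mb9",
      "label": "Containment of spills and pollutant discharge",
      "target": "q3"
    },
    {
      "id": "mb10",
      "label": "Work-injury insurance and compensation arrangements",
      "target": "q1"
    }
  ],
  "notes": "Worked example. The ten mitigative safety measures are reconstructed placeholders with the correct count; the source diagram does not enumerate them by name."
}
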