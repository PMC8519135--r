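"Timestamp (YYYY-MM-DDThh:mm:ss)","Event Type","Glucose Value (mmol/L)"
"2024-01-01T00:00:00","EGV","5.1"
"2024-01-01T00:05:00","EGV","4.9"
"2024-01-01T00:10:00","EGV","5.9"
"2024-01-01T00:15:00","EGV","5.2"
"2024-01-01T00:20:00","EGV","5.7"
"2024-01-01T00:25:00","EGV","6.1"
"2024-01-01T00:30:00","EGV","5.1"
"2024-01-01T00:35:00","EGV","5.7"
"2024-01-01T00:40:00","EGV","5.7"
"2024-01-01T00:45:00","EGV","5.5"
"2024-01-01T00:50:00","EGV","5.4"
"2024-01-01T00:55:00","EGV","5.1"
"2024-01-01T01:00:00","EGV","4.6"
"2024-01-01T01:05:00","EGV","4.9"
"2024-01-01T01:10:00","EGV","3.7"
"2024-01-01T01:15:00","EGV","3.8"
"2024-01-01T01:20:00","EGV","4.1"
"2024-01-01T01:25:00","EGV","3.6"
"2024-01-01T01:30:00","EGV","3.6"
"2024-01-01T01:35:00","EGV","3.8"
"2024-01-01T01:40:00","EGV","3.8"
"2024-01-01T01:45:00","EGV","3.9"
"2024-01-01T01:50:00","EGV","4.4"
"2024-01-01T01:55:00","EGV","4.6"
"2024-01-01T02:00:00","EGV","4.7"
"2024-01-01T02:05:00","EGV","4.6"
"2024-01-01T02:10:00","EGV","4.8"
"2024-01-01T02:15:00","EGV","4.4"
"2024-01-01T02:20:00","EGV","3.6"
"2024-01-01T02:25:00","EGV","3.7"
"2024-01-01T02:30:00","EGV","3.2"
"2024-01-01T02:35:00","EGV","3.3"
"2024-01-01T02:40:00","EGV","2.8"
"2024-01-01T02:45:00","EGV","2.4"
"2024-01-01T02:50:00","EGV","Low"
"2024-01-01T02:55:00","EGV","Low"
"2024-01-01T03:00:00","EGV","Low"
"2024-01-01T03:05:00","EGV","2.8"
"2024-01-01T03:10:00","EGV","2.7"
"2024-01-01T03:15:00","EGV","3.2"
"2024-01-01T03:20:00","EGV","3.1"
"2024-01-01T03:25:00","EGV","3.1"
"2024-01-01T03:30:00","EGV","3.8"
"2024-01-01T03:35:00","EGV","3.5"
"2024-01-01T03:40:00","EGV","3.4"
"2024-01-01T03:45:00","EGV","4.0"
"2024-01-01T03:50:00","EGV","4.5"
"2024-01-01T03:55:00","EGV","4.8"
"2024-01-01T04:00:00","EGV","5.1"
"2024-01-01T04:05:00","EGV","5.0"
"2024-01-01T04:10:00","EGV","5.7"
"2024-01-01T04:15:00","EGV","5.6"
"2024-01-01T04:20:00","EGV","5.9"
"2024-01-01T04:25:00","EGV","6.4"
"2024-01-01T04:30:00","EGV","6.2"
"2024-01-01T04:35:00","EGV","6.0"
"2024-01-01T04:40:00","EGV","6.2"
"2024-01-01T04:45:00","EGV","5.5"
"2024-01-01T04:50:00","EGV","5.2"
"2024-01-01T04:55:00","EGV","5.2"
"2024-01-01T05:00:00","EGV","4.8"
"2024-01-01T05:05:00","EGV","4.5"
"2024-01-01T05:10:00","EGV","4.1"
"2024-01-01T05:15:00","EGV","3.7"
"2024-01-01T05:20:00","EGV","4.1"
"2024-01-01T05:25:00","EGV","3.1"
"2024-01-01T05:30:00","EGV","3.9"
"2024-01-01T05:35:00","EGV","3.3"
"2024-01-01T05:40:00","EGV","4.0"
"2024-01-01T05:45:00","EGV","3.6"
"2024-01-01T05:50:00","EGV","4.4"
"2024-01-01T05:55:00","EGV","4.3"
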